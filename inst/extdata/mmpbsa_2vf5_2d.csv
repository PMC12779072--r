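# MM/PBSA end-point components for the 2VF5-2d complex (kcal/mol, +/- SD).
# polar = polar solvation (Generalized Born); nonpolar = SASA-derived.
complex,term,value_kcal_mol,sd
2VF5-2d,vdw,-42.73,0.61
2VF5-2d,ele,-22.59,3.87
2VF5-2d,polar,41.99,0.95
2VF5-2d,nonpolar,-3.98,0.04
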