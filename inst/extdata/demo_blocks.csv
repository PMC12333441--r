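"id","cycle","role","smiles"
"C1_gly",1,"fmoc_amino_acid","OC(=O)CNC(=O)OCC1c2ccccc2-c2ccccc21"
"C1_ala",1,"fmoc_amino_acid","CC(NC(=O)OCC1c2ccccc2-c2ccccc21)C(=O)O"
"C1_val",1,"fmoc_amino_acid","CC(C)C(NC(=O)OCC1c2ccccc2-c2ccccc21)C(=O)O"
"C1_leu",1,"fmoc_amino_acid","CC(C)CC(NC(=O)OCC1c2ccccc2-c2ccccc21)C(=O)O"
"C1_phe",1,"fmoc_amino_acid","OC(=O)C(Cc1ccccc1)NC(=O)OCC1c2ccccc2-c2ccccc21"
"C2_gly",2,"fmoc_amino_acid","OC(=O)CNC(=O)OCC1c2ccccc2-c2ccccc21"
"C2_ala",2,"fmoc_amino_acid","CC(NC(=O)OCC1c2ccccc2-c2ccccc21)C(=O)O"
"C2_val",2,"fmoc_amino_acid","CC(C)C(NC(=O)OCC1c2ccccc2-c2ccccc21)C(=O)O"
"C2_leu",2,"fmoc_amino_acid","CC(C)CC(NC(=O)OCC1c2ccccc2-c2ccccc21)C(=O)O"
"C2_phe",2,"fmoc_amino_acid","OC(=O)C(Cc1ccccc1)NC(=O)OCC1c2ccccc2-c2ccccc21"
"C3_benzoic",3,"capping_acid","OC(=O)c1ccccc1"
"C3_acetic",3,"capping_acid","CC(=O)O"
"C3_sulfamoylbenzoic",3,"capping_acid","NS(=O)(=O)c1ccc(C(=O)O)cc1"
"C3_imidazole4carboxylic",3,"capping_acid","OC(=O)c1c[nH]cn1"
"C1_ctrl_noacid",1,"control_no_acid",""
"C1_ctrl_noreagent",1,"control_no_reagent",""
"C2_ctrl_noacid",2,"control_no_acid",""
"C2_ctrl_noreagent",2,"control_no_reagent",""
"C3_ctrl_noacid",3,"control_no_acid",""
"C3_ctrl_noreagent",3,"control_no_reagent",""
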