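generic_label,substitution,effect,ligand,source
3x32,D3x32A,loss,all reported ligands,site-directed mutagenesis
3x33,V3x33A,decrease,all examined ligands,site-directed mutagenesis
7x42,Y7x42A,decrease,,site-directed mutagenesis
7x42,Y7x42F,loss,,site-directed mutagenesis
7x38,L7x38A,decrease,majority of cases,site-directed mutagenesis
7x38,L7x38M,no_change,one case,site-directed mutagenesis
2x64,E2x64D,mixed,ligand-dependent,site-directed mutagenesis
6x52,F6x52A,decrease,approx 1.5-fold,site-directed mutagenesis
5x43,S5x43A,mixed,ligand-dependent,site-directed mutagenesis
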