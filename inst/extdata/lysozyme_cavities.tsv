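cavity	class	residues
cavity 1	hydrophilic	28GLY,29ILE,63ALA,70ASP
cavity 2	hydrophilic	101ASN,102MET,105GLN,138TRP,149VAL
cavity 3	hydrophobic	126TRP,130ALA,153PHE,154ARG
cavity 4	hydrophobic	84LEU,87VAL,88TYR,91LEU,99ALA,102MET,111VAL,118LEU
cavity 5	random	50ILE,51GLY,52ARG,53ASN,54THR,55ASN,56GLY,57VAL,58ILE,59THR
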