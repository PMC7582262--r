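"property","source"
"helix_propensity","Chou & Fasman (1978) Adv Enzymol 47:45-148, conformational propensity"
"sheet_propensity","Chou & Fasman (1978) Adv Enzymol 47:45-148, conformational propensity"
"turn_propensity","Chou & Fasman (1978) Adv Enzymol 47:45-148, conformational propensity"
"pka_carboxyl","CRC Handbook of Chemistry and Physics, free amino acid pKa; 0.0 = no ionizable side chain"
"pka_amine","CRC Handbook of Chemistry and Physics, free amino acid pKa; 0.0 = no ionizable side chain"
"pka_side_chain","CRC Handbook of Chemistry and Physics, free amino acid pKa; 0.0 = no ionizable side chain"
"isoelectric_point","CRC Handbook of Chemistry and Physics, isoelectric point of the free amino acid"
"carbon_atoms","Atom count from the free amino acid molecular formula"
"hydrogen_atoms","Atom count from the free amino acid molecular formula"
"nitrogen_atoms","Atom count from the free amino acid molecular formula"
"oxygen_atoms","Atom count from the free amino acid molecular formula"
"sulfur_atoms","Atom count from the free amino acid molecular formula"
"heavy_atoms","Atom count from the free amino acid molecular formula"
"total_atoms","Atom count from the free amino acid molecular formula"
"residue_mass","Average molecular weight of the free amino acid, g/mol"
"surface_area","Tien et al. (2013) PLoS ONE 8:e80635, theoretical maximum accessible surface area, A^2"
"volume","Zamyatnin (1972) Prog Biophys Mol Biol 24:107-123, residue volume, A^3"
"hydropathy","Kyte & Doolittle (1982) J Mol Biol 157:105-132, hydropathy index"
"polarity","Grantham (1974) Science 185:862-864, polarity"
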