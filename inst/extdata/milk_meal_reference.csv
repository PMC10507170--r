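species,fresh_milk_g_per_kg_bw,crude_protein_g_per_kg_bw,fat_g_per_kg_bw,lactose_g_per_kg_bw,dry_matter_g_per_kg_bw,gross_energy_kcal_per_kg_bw
bovine,55.3,2.0,2.2,2.5,7.2,41.9
caprine,63.1,2.0,2.0,2.5,7.1,38.6
ovine,31.9,2.0,2.0,1.3,5.6,34.3
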