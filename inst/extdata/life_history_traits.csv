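species,guild,colony_morphology,growth_rate_mm_yr,growth_label_printed,reproductive_mode,reproductive_output,asexual_propagation,aggression,bleaching_susceptibility,sediment_tolerance
ACER,COMPETITIVE,large_branching,119.5,fast,spawner,low,high,moderate,high,low
APAL,COMPETITIVE,large_branching,68.4,fast,spawner,low,high,moderate,high,low
MILLEPORA,COMPETITIVE,plating_branching,13.2,fast,spawner,moderate,high,high,high,high
COLPOPHYLLIA,STRESS_TOLERANT,domed,7.0,moderate,spawner,low,low,high,moderate_to_low,high
PSEUDODIPLORIA,STRESS_TOLERANT,domed,5.7,moderate,spawner,low,low,moderate,low,high
MEANDRINA,STRESS_TOLERANT,domed,1.1,slow,spawner,low,low,moderate,moderate,high
MCAV,STRESS_TOLERANT,domed,5.8,moderate,spawner,low,low,moderate,low,high
ORBICELLA,STRESS_TOLERANT,domed,7.9,moderate,spawner,low,moderate_to_low,high,high,moderate_to_high
SIDERASTREA,STRESS_TOLERANT,domed,3.7,slow,mixed,low_moderate,low,low,moderate_to_high,high
STEPHANOCOENIA,STRESS_TOLERANT,domed,5.0,moderate,spawner,low_moderate,low,low,high,high
AGARICIA,WEEDY,plating_foliose,1.6,slow,brooder,high,low,low,high,moderate
PORITES_BRANCHING,WEEDY,small_branching,16.0,fast,brooder,high,high,low,moderate_to_high,high
PASTREOIDES,WEEDY,domed,4.0,slow,brooder,high,low,low,high,high
MADRACIS,WEEDY,small_branching,6.3,moderate,brooder,moderate,high,low,low,high
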