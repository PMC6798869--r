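morphospecies_id,margin_state
sp001,untoothed
sp002,untoothed
sp003,untoothed
sp004,toothed
sp005,untoothed
sp006,untoothed
sp007,toothed
sp008,untoothed
sp009,toothed
sp010,untoothed
sp011,untoothed
sp012,untoothed
sp013,untoothed
sp014,toothed
sp015,untoothed
sp016,toothed
sp017,untoothed
sp018,untoothed
sp019,untoothed
sp020,toothed
sp021,untoothed
sp022,toothed
sp023,untoothed
sp024,untoothed
sp025,untoothed
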