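dt_id,feeding_group,specialization
DT01,hole feeding,generalized
DT02,hole feeding,generalized
DT03,hole feeding,generalized
DT05,hole feeding,generalized
DT12,margin feeding,generalized
DT14,margin feeding,generalized
DT16,skeletonization,generalized
DT26,surface feeding,generalized
DT29,surface feeding,generalized
DT32,galling,specialized
DT34,galling,specialized
DT46,piercing and sucking,specialized
DT57,mining,specialized
DT62,hole feeding,generalized
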