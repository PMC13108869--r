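deployment_id,n_dives
av230803-180a,4
av230803-P48_a,1
av230803-P48_b,16
av230803-P49,15
av230805-P46_a,2
av230805-P46_b,23
av230805-P49_a,12
av230805-P49_b,5
av230806-P48,114
av230806-P49_a,11
av230806-P49_b,8
av230810-P46,17
av240809-68,3
av240809-P47,62
av240812-P48,3
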