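predicted,feeding,standing
feeding,1178,435
standing,347,1209
uncertain,36,41
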