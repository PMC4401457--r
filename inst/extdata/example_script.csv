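label,duration
stand,10
sit,10
walk,15
stairs_up,9
stairs_down,9
lie,10
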