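func	type
nonsynonymous SNV	missense
missense	missense
stopgain	stopgain
stoploss	stoploss
startloss	startloss
startlost	startloss
frameshift insertion	frameshift_insertion
frameshift deletion	frameshift_deletion
nonframeshift insertion	nonframeshift_insertion
nonframeshift deletion	nonframeshift_deletion
splicing	splicing
synonymous SNV	synonymous
synonymous	synonymous
ncRNA_exonic	ncRNA
ncRNA_splicing	ncRNA
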