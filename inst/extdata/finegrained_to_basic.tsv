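from	to
BEFORE	BEFORE
AFTER	AFTER
OVERLAP	OVERLAP
CONTAINS	OVERLAP
CONTAINED-BY	OVERLAP
BEGINS-ON	OVERLAP
ENDS-ON	BEFORE
INITIATES	OVERLAP
TERMINATES	OVERLAP
CONTINUES	OVERLAP
REINITIATES	AFTER
NOTED-ON	drop
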