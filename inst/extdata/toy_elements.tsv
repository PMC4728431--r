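motif	class
ATTTA	destabilizing
TTATTTATT	destabilizing
GTTTG	destabilizing
CCGCCC	stabilizing
AGGGA	stabilizing
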