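# The acceptance file intentionally asserts reference anchors that the
# box-model reduction cannot all reach (documented in the methods vignette);
# lift the default failure cap so a handful of honest red assertions there
# never aborts the remaining suite.
testthat::set_max_fails(Inf)
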