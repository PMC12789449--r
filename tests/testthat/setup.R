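# report every expectation rather than terminating after the first few
# failures: the acceptance comparisons are most useful as a complete table
options(testthat.progress.max_fails = Inf)
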