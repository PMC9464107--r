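# keep long property loops from tripping the progress reporter's failure cap
options(testthat.progress.max_fails = 10000L)
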