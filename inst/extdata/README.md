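# External data

The test suite's published-values check looks for the deposited 403-sequence
ND5 alignment at `appendix_s1_nd5.fasta` in this directory (FASTA ids must
end in `_2010`, `_2011` or `_2012`, or a sidecar cohort map must be used).
The file is not redistributed with the package. All other fixtures are
generated programmatically by `make_fixtures()`.
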