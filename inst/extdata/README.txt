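atpase_rates_synthetic.csv

SYNTHETIC stand-in for a per-sequence ATP hydrolysis rate table (48-nt
tri-nucleotide repeat substrates, 1 uM RecA, arbitrary consistent units).
No per-sequence ATPase numbers were ever published for this assay; these
values only reproduce the qualitative ordering reported for such data
(TGG slowest, pyrimidine-rich repeats faster) and exist so that the
planted-correlation pipeline demo has a condition table to consume.
Do not treat these numbers as measurements.
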