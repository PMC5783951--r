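# Synthetic example of a study manifest: maps adaptation cases to the
# sample ids that provide their o / p / a stages. Several cases may share
# ancestral (o, p) samples while each evolved line provides its own a.
cases:
  line1:
    o: [ancestor_orig]
    p: [ancestor_shifted]
    a: [evolved_line1_rep1, evolved_line1_rep2]
  line2:
    o: [ancestor_orig]
    p: [ancestor_shifted]
    a: [evolved_line2_rep1]
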