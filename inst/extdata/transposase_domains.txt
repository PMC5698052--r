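# Transposase / transposable-element-related Pfam domains filtered from
# predicted gene sets. Edit or replace via filter_gene_set(blocklist = ...).
PF00078
PF00665
PF00872
PF01359
PF01609
PF02371
PF03004
PF03017
PF03732
PF04827
PF05699
PF07727
PF10551
PF13837
PF13843
PF13963
PF14372
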