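Place real study inputs here to run the conditional published-data checks
in the test suite:

  agaricia_mitogenomes_aligned.fasta   two aligned Agaricia mitochondrial
                                       genomes (GenBank KM051016, DQ643831)
  agaricia_mitogenomes_regions.bed     coding/ribosomal region annotation
                                       on the alignment coordinate system
  scleractinia_cyb_survey.nex          the published cytochrome b survey
                                       alignment (NEXUS)

These are third-party data and are not redistributed with the package;
all other fixtures are generated in code.
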