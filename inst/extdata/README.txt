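Plain-text fixtures.

up_overlap_genes.txt   - 11 upregulated genes replicated across all three
                         knockdown cell models (published triple overlap).
down_overlap_genes.txt - 7 downregulated genes replicated across all three
                         models.

The full per-model target lists (174 up / 75 down in the focal model) are not
public; tests reconstruct sets of those sizes by padding the printed overlap
genes with clearly SYNTHETIC filler symbols (UPFILL###/DNFILL###). Only the
overlap genes and the set sizes are real.
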