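# Bundled cis-element dictionary (editable).
# Columns: name, motif (IUPAC), source.
# Entries marked "external-literature, editable" carry canonical literature
# consensus sequences, not experimentally re-verified here; all-N motifs are
# placeholders for bait elements whose sequence is not published in the main
# text — replace them before relying on scan results.
name	motif	source
DRE	RCCGAC	external-literature, editable: DREB core A/GCCGAC
DRE-like	CCTACC	enriched hexamer, DRE-like variant
CCCCAC	CCCCAC	enriched hexamer, DRE-like variant
ARR1AT	GTKATT	enriched hexamer variants GTTATT/GTGATT unified
MYBST1	TATCCC	enriched hexamer, MYB-ST1 binding site
BOXIII	CATTT	enriched element, box III core
New3	CGTCCA	novel enriched hexamer (yeast one-hybrid bait New3)
New4	TTCTCT	novel enriched hexamer (yeast one-hybrid bait New4)
CATTTT	CATTTT	high-frequency hexamer in lignin/sugar pathway promoters
AAACAA	AAACAA	high-frequency hexamer in lignin/sugar pathway promoters
TTTCTC	TTTCTC	high-frequency hexamer in lignin/sugar pathway promoters
TCTTTT	TCTTTT	high-frequency hexamer in lignin/sugar pathway promoters
GCC	GCCGCC	external-literature, editable: GCC-box consensus
ABRE	ACGTGKC	external-literature, editable: ABRE core ACGTG(G/T)C
MYBCORE	CNGTTR	external-literature, editable: MYB core consensus
AuxRR	GGTCCAT	external-literature, editable: auxin-responsive region core
CE3	ACGCGTG	external-literature, editable: coupling element 3 core
obo-Box	NNNNNN	placeholder: bait sequence not published in main text
New1	NNNNNN	placeholder: bait sequence not published in main text
New2	NNNNNN	placeholder: bait sequence not published in main text
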