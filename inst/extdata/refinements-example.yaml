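# Example refinement override file.
#
# Refinement encodes judgment-driven dual category memberships decided
# after inspecting the tSNE diagram and domain knowledge: each entry
# ADDS categories to a disease, never removes one. Disease ids and
# category names must exist in the preliminary assignment.
#
# The ids below match the synthetic generator's naming
# (see generate_gene_sets()); replace them with your own disease ids.
additions:
  D001:
    - CATG-2
  D011:
    - CATG-1
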