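# Per-class genomic-context rules for precursor validity assignment.
#
# defining_domains: accessions or name fragments of class-defining PTM
#   enzyme domains searched in the precursor's gene neighborhood. The
#   graspetide entry is an annotation keyword ("ATP-grasp").
# residue_groups: conjunction of residue groups; the precursor must
#   contain at least one residue from every group (e.g. lanthipeptide
#   needs Cys AND Ser-or-Thr to form the lanthionine/labionin ring).
# intrinsic_aa_required: classes with `false` lack intrinsic amino-acid
#   requirements and are only eligible for the RiPP-related or None
#   validity levels, never PTM or AA.
#
# Entries marked `provisional: true` are package defaults chosen from
# general RiPP biosynthesis knowledge, not a published per-class table;
# override via the `rules` argument where a curated table is available.
classes:
  "autoinducing peptide":
    defining_domains: [PF04647, AgrB]
    residue_groups: []
    intrinsic_aa_required: false
  "bacterial head-to-tail cyclized peptide":
    defining_domains: [PF01944, DUF95]
    residue_groups: []
    intrinsic_aa_required: false
  "cyanobactin":
    defining_domains: [PF00082, PatA, PatG]
    residue_groups: []
    intrinsic_aa_required: false
  "graspetide":
    defining_domains: [ATP-grasp]
    residue_groups: [["D", "E"]]
    intrinsic_aa_required: true
    provisional: true
  "lanthipeptide":
    defining_domains: [PF05147, PF04738, PF14028, LANC_like, DUF4135]
    residue_groups: [["C"], ["S", "T"]]
    intrinsic_aa_required: true
  "lasso peptide":
    defining_domains: [PF13471, PF05402, Transglut_core3]
    residue_groups: [["E", "D"]]
    intrinsic_aa_required: true
    provisional: true
  "other RiPPs":
    defining_domains: []
    residue_groups: []
    intrinsic_aa_required: false
  "rSAM-modified peptide":
    defining_domains: [PF04055, Radical_SAM]
    residue_groups: [["C"]]
    intrinsic_aa_required: true
    provisional: true
  "thiopeptide":
    defining_domains: [PF02624, YcaO]
    residue_groups: [["C", "S", "T"]]
    intrinsic_aa_required: true
    provisional: true
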