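# Hand-constructed segment pairs with hand-derived verdicts under the
# reference parameter set (cut 2, lmin 2.5, lmax 3, lmax.line 4).
congruence_truth_table <- function() {
  list(
    # identical segments: everything zero, congruent
    list(s1 = c(0, 0, 4, 0), s2 = c(0, 0, 4, 0),
         congruent = TRUE, pattern = "FULL_OVERLAP"),
    # parallel at offset 1: full overlap, well within every bound
    list(s1 = c(0, 0, 4, 0), s2 = c(0, 1, 4, 1),
         congruent = TRUE, pattern = "FULL_OVERLAP"),
    # parallel at offset 3.5: full overlap, dmax_line 3.5 <= 4 passes
    # rule 2 although dmin 3.5 > lmin 2.5 fails rule 1
    list(s1 = c(0, 0, 4, 0), s2 = c(0, 3.5, 4, 3.5),
         congruent = TRUE, pattern = "FULL_OVERLAP", rule = "RULE2"),
    # parallel at offset 4.5: full overlap but beyond lmax.line too
    list(s1 = c(0, 0, 4, 0), s2 = c(0, 4.5, 4, 4.5),
         congruent = FALSE, pattern = "FULL_OVERLAP"),
    # collinear disjoint, gap 6: no feet, never congruent
    list(s1 = c(0, 0, 4, 0), s2 = c(10, 0, 14, 0),
         congruent = FALSE, pattern = "NONE"),
    # collinear disjoint, tiny gap 0.5: still no feet
    list(s1 = c(0, 0, 4, 0), s2 = c(4.5, 0, 8.5, 0),
         congruent = FALSE, pattern = "NONE"),
    # collinear touching at a shared endpoint: boundary foot, dmin 0,
    # dmax 4 > lmax 3 fails rule 1; no full overlap
    list(s1 = c(0, 0, 4, 0), s2 = c(4, 0, 8, 0),
         congruent = FALSE, pattern = "PARTIAL"),
    # collinear overlapping by 2: partial, dmin 0, dmax 2 <= 3: rule 1
    list(s1 = c(0, 0, 4, 0), s2 = c(2, 0, 6, 0),
         congruent = TRUE, pattern = "PARTIAL", rule = "RULE1"),
    # staggered parallel at offset 2: one foot each way; dmin 2 <= 2.5
    # but dmax = |(8,2)-(4,0)| = sqrt(20) > 3: fails
    list(s1 = c(0, 0, 4, 0), s2 = c(3, 2, 8, 2),
         congruent = FALSE, pattern = "PARTIAL"),
    # short staggered parallel at offset 2: dmin 2,
    # dmax = |(0,0)-(3,2)| = sqrt(13) > 3: fails rule 1
    list(s1 = c(0, 0, 4, 0), s2 = c(3, 2, 5, 2),
         congruent = FALSE, pattern = "PARTIAL"),
    # short parallel at offset 1 inside s1's span: full overlap of s2,
    # dmax_line = 1 <= 4: rule 2 fires (checked before rule 1)
    list(s1 = c(0, 0, 4, 0), s2 = c(1, 1, 3, 1),
         congruent = TRUE, pattern = "FULL_OVERLAP", rule = "RULE2"),
    # perpendicular spear over the interior: both endpoints of the
    # vertical segment project onto s1, so full overlap, but
    # dmax_line = 5 > 4 and dmax = 5 > 3: both rules fail
    list(s1 = c(0, 0, 4, 0), s2 = c(2, 1, 2, 5),
         congruent = FALSE, pattern = "FULL_OVERLAP"),
    # short perpendicular stub over the interior: feet of both its
    # endpoints -> full overlap, dmax_line = 2 <= 4: rule 2
    list(s1 = c(0, 0, 4, 0), s2 = c(2, 1, 2, 2),
         congruent = TRUE, pattern = "FULL_OVERLAP", rule = "RULE2"),
    # symmetric X crossing: all four feet at the centre at distance
    # sqrt(8) ~ 2.83 > lmin so rule 1 fails, but full overlap with
    # dmax_line = sqrt(8) <= 4: rule 2
    list(s1 = c(-2, -2, 2, 2), s2 = c(-2, 2, 2, -2),
         congruent = TRUE, pattern = "FULL_OVERLAP", rule = "RULE2")
  )
}
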