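# Per-case mutation and match counts for the 49 contralateral breast
# cancer cases (254-gene panel), with the identities of the matched
# loci.  `left`/`right` are total somatic mutation counts per tumor,
# matches included, so a case contributes `left + right - 2 * matches`
# private loci.
contralateral_breast_counts_tbl <- function() {
  tibble::tibble(
    case_id = c(1, 2, 3, 4, 6, 8, 9, 12, 13, 15, 16, 17, 18, 21, 23,
                24, 25, 26, 27, 29, 30, 31, 32, 33, 35, 36, 38, 40, 41,
                43, 44, 45, 48, 52, 56, 58, 59, 62, 63, 64, 66, 67, 70,
                71, 72, 74, 75, 76, 77),
    left = c(9, 3, 2, 8, 6, 6, 2, 14, 3, 8, 10, 6, 8, 4, 10, 4, 4, 6,
             4, 3, 6, 6, 5, 6, 5, 3, 8, 10, 0, 4, 9, 3, 2, 5, 2, 3, 2,
             4, 3, 5, 3, 4, 5, 3, 1, 2, 4, 7, 3),
    right = c(7, 3, 7, 10, 5, 2, 3, 3, 3, 5, 8, 8, 2, 3, 4, 3, 6, 5,
              5, 1, 5, 5, 4, 4, 4, 4, 2, 1, 9, 4, 21, 4, 3, 7, 5, 4,
              3, 4, 9, 4, 33, 1, 2, 1, 3, 1, 3, 5, 1),
    matches = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                0, 0, 0, 0, 0, 0, 0, 3, 0, 0, 0, 0, 0, 0, 2, 0, 0, 0,
                0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0)
  )
}

# Matched loci with their reported identities.  `rare` marks loci whose
# occurrence probability is reported only as "< 1/1000"; the three
# PIK3CA H1047R hotspot matches have p = 0.137.
contralateral_breast_matches_tbl <- function() {
  tibble::tibble(
    case_id = c(8, 36, 36, 36, 48, 48, 63, 67, 75),
    gene_label = c("ARID1A E250fs", "CDH1 S111fs", "TBX3 T267fs",
                   "EPPK1 R2337H", "MLH3 M346R", "MAP3K1 R248*",
                   "PIK3CA H1047R", "PIK3CA H1047R", "PIK3CA H1047R"),
    rare = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' The 49-case contralateral breast cancer dataset
#'
#' A per-locus case table for the study of 49 women with presumed
#' contralateral breast cancer whose tumor pairs were sequenced with a
#' 254-gene panel.  Six cases have at least one mutational match;
#' three of the matches (cases 63, 67, 75) are at the common PIK3CA
#' H1047R hotspot (`p = 0.137`) and the remaining matches (cases 8,
#' 36, 48) are at rare loci whose occurrence probability is known only
#' to be below 1/1000.
#'
#' Only the matched loci are published with identities and
#' probabilities.  Rare matched loci are assigned `p_rare` (default
#' `1e-3`, the reported upper bound — a conservative choice that
#' weakens, never strengthens, the rare-match evidence).  The
#' unmatched mutations are materialized as anonymous private loci
#' (`L1`, `L2`, ...) with probability `p_private` (default `1e-3`);
#' the likelihood is insensitive to private-locus `p` when it is small
#' because the private term depends on `p` only through `1 - p`
#' factors.  Per-tumor totals match the published counts exactly.
#'
#' @param p_rare Probability assigned to matched loci reported as
#'   "< 1/1000".
#' @param p_private Probability assigned to the (unpublished) private
#'   loci.
#' @param p_hotspot Probability of the PIK3CA H1047R hotspot
#'   (default 0.137).
#' @return A per-locus case table tibble (see [as_case_table()]) with
#'   49 cases.
#' @examples
#' tbl <- contralateral_breast_cases()
#' dplyr::n_distinct(tbl$case_id)
#' @export
contralateral_breast_cases <- function(p_rare = 1e-3, p_private = 1e-3,
                                       p_hotspot = 0.137) {
  counts <- contralateral_breast_counts_tbl()
  matches <- contralateral_breast_matches_tbl()
  rows <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    cs <- counts[i, ]
    m <- matches[matches$case_id == cs$case_id, ]
    stopifnot(nrow(m) == cs$matches)
    shared <- if (nrow(m)) {
      tibble::tibble(
        case_id = as.character(cs$case_id),
        locus_id = paste0("M", seq_len(nrow(m))),
        gene_label = m$gene_label,
        p = ifelse(m$rare, p_rare, p_hotspot),
        in_tumor1 = 1L, in_tumor2 = 1L
      )
    } else {
      NULL
    }
    n1 <- cs$left - cs$matches    # private loci seen in tumor 1
    n2 <- cs$right - cs$matches   # private loci seen in tumor 2
    private <- if (n1 + n2 > 0) {
      tibble::tibble(
        case_id = as.character(cs$case_id),
        locus_id = paste0("L", seq_len(n1 + n2)),
        gene_label = NA_character_,
        p = p_private,
        in_tumor1 = rep(c(1L, 0L), c(n1, n2)),
        in_tumor2 = rep(c(0L, 1L), c(n1, n2))
      )
    } else {
      NULL
    }
    dplyr::bind_rows(shared, private)
  })
  as_case_table(rows)
}
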