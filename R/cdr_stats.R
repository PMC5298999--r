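# Region-level comparative statistics: VH vs VL dominance, paired
# CDR1+2 vs CDR3 comparisons (BSA, IVW-IPL, ANSO) by Wilcoxon signed-rank
# tests, and CDR length-vs-BSA tables.

.vh_regions <- function() paste0("VH-", c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"))
.vl_regions <- function() paste0("VL-", c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"))

.region_col <- function(desc, what, region) {
  col <- paste0(what, "_", gsub("-", "_", region, fixed = TRUE))
  if (!col %in% names(desc)) stop("descriptor table lacks column ", col)
  desc[[col]]
}

.domain_bsa <- function(desc, chain) {
  regions <- if (chain == "VH") .vh_regions() else .vl_regions()
  Reduce(`+`, lapply(regions, function(rg) .region_col(desc, "bsa", rg)))
}

#' Fraction of complexes whose VH buries more surface than VL
#'
#' @param desc flat descriptor table from [descriptor_table()]
#' @return fraction of complexes with `BSA(VH) > BSA(VL)` (strict)
#' @export
vh_vl_dominance <- function(desc) {
  mean(.domain_bsa(desc, "VH") > .domain_bsa(desc, "VL"))
}

#' Paired CDR1+2 vs CDR3 region table
#'
#' One row per (complex, chain, metric) with `v12` (CDR1 + CDR2) and `v3`
#' (CDR3). For BSA and IVW-IPL, `v12` is the sum of the two regions; for
#' ANSO it is computed on the pooled CDR1 and CDR2 interface-atom sets,
#' `(IVW-IPL_1 + IVW-IPL_2) / (|A_1| + |A_2|)`. Pairs where ANSO is
#' undefined (no interface atoms on one side of the pair) are dropped with a
#' message.
#'
#' @param desc flat descriptor table from [descriptor_table()]
#' @param metrics metrics to tabulate
#' @return data frame: `complex_id`, `chain`, `metric`, `v12`, `v3`
#' @export
paired_region_table <- function(desc,
                                metrics = c("BSA", "IVW-IPL", "ANSO")) {
  rows <- list()
  dropped <- 0L
  for (chain in c("VH", "VL")) {
    r1 <- paste0(chain, "-CDR1"); r2 <- paste0(chain, "-CDR2")
    r3 <- paste0(chain, "-CDR3")
    for (metric in metrics) {
      if (metric == "BSA") {
        v12 <- .region_col(desc, "bsa", r1) + .region_col(desc, "bsa", r2)
        v3 <- .region_col(desc, "bsa", r3)
      } else if (metric == "IVW-IPL") {
        v12 <- .region_col(desc, "ivw_ipl", r1) + .region_col(desc, "ivw_ipl", r2)
        v3 <- .region_col(desc, "ivw_ipl", r3)
      } else if (metric == "ANSO") {
        n12 <- .region_col(desc, "n_atoms", r1) + .region_col(desc, "n_atoms", r2)
        n3 <- .region_col(desc, "n_atoms", r3)
        v12 <- ifelse(n12 > 0,
                      (.region_col(desc, "ivw_ipl", r1) +
                         .region_col(desc, "ivw_ipl", r2)) / n12, NA_real_)
        v3 <- ifelse(n3 > 0,
                     .region_col(desc, "ivw_ipl", r3) / n3, NA_real_)
      } else {
        stop("unknown metric: ", metric)
      }
      keep <- !is.na(v12) & !is.na(v3)
      dropped <- dropped + sum(!keep)
      rows[[paste(chain, metric)]] <- data.frame(
        complex_id = desc$complex_id[keep], chain = chain, metric = metric,
        v12 = v12[keep], v3 = v3[keep], stringsAsFactors = FALSE
      )
    }
  }
  if (dropped > 0) {
    message(dropped, " (complex, chain, metric) pair(s) dropped (undefined ANSO)")
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Paired Wilcoxon signed-rank tests, CDR1+2 vs CDR3
#'
#' For every (chain, metric) group, zero differences are dropped, then the
#' standard signed-rank test is run two-sided: exact null distribution for
#' up to 25 non-tied pairs, normal approximation with continuity correction
#' otherwise. The descriptive fraction of complexes with `v12 > v3` (strict,
#' over all pairs) is reported alongside.
#'
#' @param table a [paired_region_table()] data frame
#' @param exact_max_n largest number of non-zero pairs for which the exact
#'   distribution is used
#' @return data frame: `chain`, `metric`, `n_pairs`, `n_nonzero`,
#'   `frac_v12_gt_v3`, `p_value`, `status`
#' @export
paired_wilcoxon <- function(table, exact_max_n = 25) {
  groups <- unique(table[, c("chain", "metric")])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- table[table$chain == groups$chain[g] &
                   table$metric == groups$metric[g], , drop = FALSE]
    diffs <- sub$v12 - sub$v3
    nz <- diffs[diffs != 0]
    frac <- mean(sub$v12 > sub$v3)
    if (length(nz) == 0) {
      warning(sprintf("all pairs tied for %s/%s: test undefined",
                      groups$chain[g], groups$metric[g]), call. = FALSE)
      p <- NA_real_
      status <- "undefined"
    } else {
      wt <- suppressWarnings(wilcox.test(
        nz, alternative = "two.sided",
        exact = length(nz) <= exact_max_n, correct = TRUE
      ))
      p <- wt$p.value
      status <- if (length(nz) <= exact_max_n) "exact" else "normal-cc"
    }
    data.frame(chain = groups$chain[g], metric = groups$metric[g],
               n_pairs = nrow(sub), n_nonzero = length(nz),
               frac_v12_gt_v3 = frac, p_value = p, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' CDR length versus buried surface area
#'
#' One row per (complex, chain, region group), with the [CDR1+CDR2] pair and
#' CDR3 reported separately. Region length is the residue count within the
#' annotated region limits; no aggregation across complexes.
#'
#' @param desc flat descriptor table from [descriptor_table()]
#' @return data frame: `complex_id`, `chain`, `group`, `length`, `bsa`
#' @export
length_vs_bsa <- function(desc) {
  rows <- list()
  for (chain in c("VH", "VL")) {
    r1 <- paste0(chain, "-CDR1"); r2 <- paste0(chain, "-CDR2")
    r3 <- paste0(chain, "-CDR3")
    rows[[paste(chain, "12")]] <- data.frame(
      complex_id = desc$complex_id, chain = chain, group = "CDR1+CDR2",
      length = .region_col(desc, "n_residues", r1) +
        .region_col(desc, "n_residues", r2),
      bsa = .region_col(desc, "bsa", r1) + .region_col(desc, "bsa", r2),
      stringsAsFactors = FALSE
    )
    rows[[paste(chain, "3")]] <- data.frame(
      complex_id = desc$complex_id, chain = chain, group = "CDR3",
      length = .region_col(desc, "n_residues", r3),
      bsa = .region_col(desc, "bsa", r3),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
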