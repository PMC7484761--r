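#' Select the DKD-associated proteins from the Set1 comparison
#'
#' DKD-associated glomerular proteins (DKD-GPs) are those significant in the
#' DKD-vs-WT comparison, split by the sign of their log2 fold change. A
#' significant protein with log2fc exactly 0 cannot be oriented and is
#' excluded with a warning (impossible under continuous data).
#'
#' @param res1 Set1 result tibble from [run_comparison()].
#' @return List with character vectors `up` and `down` of protein ids.
#' @export
select_dkd_gps <- function(res1) {
  sig <- dplyr::filter(res1, .data$significant)
  zero <- sig$log2fc == 0
  if (any(zero)) {
    warn(sprintf("%d significant protein(s) with log2fc == 0 excluded from the DKD sets",
                 sum(zero)))
    sig <- sig[!zero, ]
  }
  list(up = sig$protein_id[sig$log2fc > 0],
       down = sig$protein_id[sig$log2fc < 0])
}

# named lookup helpers over the union of compared proteins; a protein absent
# from a comparison (failed its quantification filter) is "not significant"
# there, and its fold-change sign is 0
sig_lookup <- function(res, universe) {
  v <- setNames(rep(FALSE, length(universe)), universe)
  v[res$protein_id] <- res$significant
  v
}

sign_lookup <- function(res, universe) {
  v <- setNames(rep(0, length(universe)), universe)
  v[res$protein_id] <- sign(res$log2fc)
  v
}

#' Ramipril-insensitive / ramipril-sensitive signature selection
#'
#' Implements the selection flowchart classifying the DKD-associated proteins
#' (significant in Set1, DKD vs WT) by their behavior under ramipril:
#'
#' * **RI (ramipril-insensitive)**: not significant in Set2 (DKD+R vs DKD) —
#'   Filter 3 — and, of those candidates, proteins also significantly varying
#'   in Set3 (WT+R vs WT) are removed as ramipril-sensitive in non-diabetic
#'   animals — Filter 4.
#' * **RS (ramipril-sensitive)**: significant in Set2 with the opposite trend
#'   to Set1 (counter-regulated) — Filter 1 — and, of those candidates,
#'   proteins whose Set3 behavior shows a ramipril sensitivity not specific to
#'   DKD are removed — Filter 2.
#'
#' The Filter 2 pattern is configurable because the source description is
#' ambiguous: `"same_sign"` (default) removes candidates significant in Set3
#' with the same trend as their Set2 change (the ramipril effect reproduced in
#' non-diabetic mice); `"opposite_sign"` is the literal opposite-trend
#' reading; `"any"` removes any Set3-significant candidate.
#'
#' Proteins absent from a comparison (failed its quantification filter) count
#' as not significant there; their number is recorded in `n_absent_set2` /
#' `n_absent_set3`.
#'
#' @param res1,res2,res3 result tibbles from [run_comparison()] for Set1
#'   (DKD vs WT), Set2 (DKD+R vs DKD) and Set3 (WT+R vs WT).
#' @param filter2 Filter 2 policy, see above.
#' @return An object of class `signature_sets` with fields `dkd_up`,
#'   `dkd_down`, `ri_up`, `ri_down`, `rs_up`, `rs_down` (protein-id vectors)
#'   and `trace`, a named integer vector of flowchart counts
#'   (`n_set1_sig`, `n_set2_nonsig`, `n_filter3_candidates`,
#'   `n_filter4_removed`, `n_ri_final`, `n_set2_sig`, `n_filter1_candidates`,
#'   `n_filter2_removed`, `n_rs_final`).
#' @seealso [flowchart_report()], [tidy.signature_sets()],
#'   [glance.signature_sets()]
#' @export
select_signatures <- function(res1, res2, res3,
                              filter2 = c("same_sign", "opposite_sign", "any")) {
  filter2 <- match.arg(filter2)
  dkd <- select_dkd_gps(res1)
  dkd_all <- c(dkd$up, dkd$down)
  universe <- unique(c(res1$protein_id, res2$protein_id, res3$protein_id))

  sig2 <- sig_lookup(res2, universe)
  sig3 <- sig_lookup(res3, universe)
  sgn1 <- sign_lookup(res1, universe)
  sgn2 <- sign_lookup(res2, universe)
  sgn3 <- sign_lookup(res3, universe)

  # --- RI branch: Filter 3 keeps Set2-non-significant DKD-GPs, Filter 4
  #     removes those significantly varying in Set3
  ri_cand <- dkd_all[!sig2[dkd_all]]
  ri_removed <- ri_cand[sig3[ri_cand]]
  ri <- setdiff(ri_cand, ri_removed)

  # --- RS branch: Filter 1 keeps Set2-significant DKD-GPs counter-regulated
  #     relative to Set1, Filter 2 removes the configured non-DKD-specific
  #     ramipril-sensitivity pattern in Set3
  rs_cand <- dkd_all[sig2[dkd_all] & sgn2[dkd_all] == -sgn1[dkd_all]]
  rs_removed <- switch(filter2,
    same_sign = rs_cand[sig3[rs_cand] & sgn3[rs_cand] == sgn2[rs_cand]],
    opposite_sign = rs_cand[sig3[rs_cand] & sgn3[rs_cand] == -sgn2[rs_cand]],
    any = rs_cand[sig3[rs_cand]]
  )
  rs <- setdiff(rs_cand, rs_removed)

  trace <- c(
    n_set1_sig = length(dkd_all),
    n_set2_nonsig = length(universe) - sum(sig2),
    n_filter3_candidates = length(ri_cand),
    n_filter4_removed = length(ri_removed),
    n_ri_final = length(ri),
    n_set2_sig = sum(sig2),
    n_filter1_candidates = length(rs_cand),
    n_filter2_removed = length(rs_removed),
    n_rs_final = length(rs)
  )

  out <- list(
    dkd_up = dkd$up, dkd_down = dkd$down,
    ri_up = intersect(ri, dkd$up), ri_down = intersect(ri, dkd$down),
    rs_up = intersect(rs, dkd$up), rs_down = intersect(rs, dkd$down),
    trace = trace,
    n_absent_set2 = sum(!dkd_all %in% res2$protein_id),
    n_absent_set3 = sum(!dkd_all %in% res3$protein_id),
    filter2 = filter2
  )
  stopifnot(
    length(out$ri_up) + length(out$ri_down) == trace[["n_ri_final"]],
    length(out$rs_up) + length(out$rs_down) == trace[["n_rs_final"]],
    trace[["n_ri_final"]] == trace[["n_filter3_candidates"]] - trace[["n_filter4_removed"]],
    trace[["n_rs_final"]] == trace[["n_filter1_candidates"]] - trace[["n_filter2_removed"]],
    length(intersect(ri, rs)) == 0
  )
  structure(out, class = "signature_sets")
}

#' Flowchart trace report
#'
#' Emits the ordered selection-flowchart counts together with the RI fraction,
#' `100 * |RI| / |DKD-GP|` truncated to an integer percentage (`NA` when no
#' DKD-GPs exist).
#'
#' @param sets a `signature_sets` object.
#' @param file optional path; when given, the trace tibble is also written as
#'   TSV.
#' @param quiet suppress console output.
#' @return Tibble with columns `step` and `count` (plus the RI fraction row),
#'   invisibly.
#' @export
flowchart_report <- function(sets, file = NULL, quiet = FALSE) {
  stopifnot(inherits(sets, "signature_sets"))
  n_dkd <- sets$trace[["n_set1_sig"]]
  ri_fraction <- if (n_dkd > 0) {
    floor(100 * sets$trace[["n_ri_final"]] / n_dkd)
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    step = c(names(sets$trace), "ri_fraction_pct"),
    count = c(unname(sets$trace), ri_fraction)
  )
  if (!quiet) {
    cat(sprintf("DKD-GPs (Set1 significant): %d (%d up / %d down)\n",
                n_dkd, length(sets$dkd_up), length(sets$dkd_down)))
    cat(sprintf("RI: %d Set2-non-significant candidates - %d Set3-significant = %d final (%d up / %d down)\n",
                sets$trace[["n_filter3_candidates"]],
                sets$trace[["n_filter4_removed"]],
                sets$trace[["n_ri_final"]],
                length(sets$ri_up), length(sets$ri_down)))
    cat(sprintf("RS: %d counter-regulated candidates - %d non-DKD-specific = %d final (%d up / %d down)\n",
                sets$trace[["n_filter1_candidates"]],
                sets$trace[["n_filter2_removed"]],
                sets$trace[["n_rs_final"]],
                length(sets$rs_up), length(sets$rs_down)))
    cat(sprintf("RI fraction of DKD-GPs: %s%%\n",
                ifelse(is.na(ri_fraction), "undefined", ri_fraction)))
  }
  if (!is.null(file)) readr::write_tsv(out, file)
  invisible(out)
}

#' @export
print.signature_sets <- function(x, ...) {
  cat("<signature_sets>\n")
  flowchart_report(x)
  invisible(x)
}

#' Tidy a signature-set object
#'
#' @param x a `signature_sets` object.
#' @param ... unused.
#' @return Long tibble `protein_id`, `signature` (`dkd`/`ri`/`rs`),
#'   `direction` (`up`/`down`).
#' @export
tidy.signature_sets <- function(x, ...) {
  purrr::map(c("dkd", "ri", "rs"), function(sg) {
    purrr::map(c("up", "down"), function(d) {
      ids <- x[[paste(sg, d, sep = "_")]]
      if (length(ids) == 0) return(NULL)
      tibble::tibble(protein_id = ids, signature = sg, direction = d)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Glance at a signature-set object
#'
#' @param x a `signature_sets` object.
#' @param ... unused.
#' @return One-row tibble of all flowchart counts plus `ri_fraction_pct`.
#' @export
glance.signature_sets <- function(x, ...) {
  tr <- tibble::as_tibble(as.list(x$trace))
  tr$ri_fraction_pct <- if (tr$n_set1_sig > 0) {
    floor(100 * tr$n_ri_final / tr$n_set1_sig)
  } else {
    NA_real_
  }
  tr
}
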