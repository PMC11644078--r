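#' Construct a ranked metabolite list
#'
#' Orders metabolites by decreasing ranking score (typically the OPLS-DA
#' predictive loadings) for preranked set enrichment.
#'
#' @param scores Named numeric vector (metabolite -> score). Names must be
#'   unique.
#' @return Named numeric vector sorted non-increasing, class `ranked_list`.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stopf("scores must be uniquely named")
  }
  if (anyNA(scores)) stopf("scores must not contain NA")
  out <- sort(scores, decreasing = TRUE)
  class(out) <- c("ranked_list", class(out))
  out
}

#' Weighted running-sum enrichment score
#'
#' The GSEA-style statistic: walking down the ranked list, member hits
#' increment the running sum by `|score|^weight` (normalized over members)
#' and misses decrement it by `1/(N - n_members)`; the enrichment score is
#' the signed extremum of the running sum. Always in `[-1, 1]`. A set
#' covering the whole list (no misses) is degenerate and rejected.
#'
#' @param ranked A [ranked_list()].
#' @param members Character vector of member metabolite names.
#' @param weight Exponent on `|score|` for hit increments (default 1).
#' @return The enrichment score (numeric scalar).
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  idx <- which(names(ranked) %in% members)
  N <- length(ranked)
  nm <- length(idx)
  if (nm == 0) stopf("no member of the set is present in the ranked list")
  if (nm == N) stopf("set covers the entire ranked list (no misses); degenerate")
  es_from_hits(sort(idx), abs(as.numeric(ranked))^weight, N)
}

# Core running-sum extremum from sorted hit positions. The running sum is
# piecewise linear, so it suffices to evaluate it at each hit (local maxima)
# and just before each hit (local minima); it starts and ends at 0.
es_from_hits <- function(idx, absw, N) {
  nm <- length(idx)
  w <- absw[idx]
  sw <- sum(w)
  if (sw == 0) w[] <- 1 / nm else w <- w / sw
  dec <- 1 / (N - nm)
  cum <- cumsum(w)
  miss_before <- idx - seq_len(nm)           # misses preceding each hit
  val_before <- c(0, cum[-nm]) - miss_before * dec
  val_at <- cum - miss_before * dec
  es_pos <- max(val_at)
  es_neg <- min(c(val_before, 0))
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Metabolite-set enrichment analysis on a ranked list
#'
#' For each pathway, computes the running-sum enrichment score of its
#' members in the profile, a permutation null from random member sets of
#' equal size drawn from the ranked list, a normalized enrichment score
#' (`es` divided by the mean `|es|` of same-signed null draws), a signed
#' tail p-value and Benjamini-Hochberg adjusted p across pathways. Pathways
#' with fewer than `min_size` members present in the profile are skipped
#' and reported in the `skipped` attribute.
#'
#' @param ranked A [ranked_list()].
#' @param annotation A [pathway_annotation()].
#' @param n_perm Number of null permutations (>= 100).
#' @param min_size Minimal set size after intersection with the profile.
#' @param weight Hit-weight exponent, as in [enrichment_score()].
#' @param seed Integer seed; results are deterministic given the seed.
#' @return `data.frame` with columns `pathway_id`, `size`, `es`, `nes`,
#'   `p_raw`, `p_adj`, `direction`; attribute `skipped` lists pathways
#'   below `min_size`.
#' @export
msea <- function(ranked, annotation, n_perm = 1000, min_size = 3,
                 weight = 1, seed = 1) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(annotation, "pathway_annotation"))
  if (n_perm < 100) stopf("n_perm must be at least 100")
  N <- length(ranked)
  absw <- abs(as.numeric(ranked))^weight
  member_idx <- lapply(annotation$sets, function(s) which(names(ranked) %in% s))
  sizes <- lengths(member_idx)
  skipped <- names(annotation$sets)[sizes < min_size | sizes >= N]
  keep <- setdiff(names(annotation$sets), skipped)
  if (!length(keep)) {
    out <- data.frame(pathway_id = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), direction = character(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  with_seed(seed, {
    # one shared null per distinct set size
    null_by_size <- new.env()
    for (sz in unique(sizes[keep])) {
      nulls <- vapply(seq_len(n_perm), function(i) {
        es_from_hits(sort(sample.int(N, sz)), absw, N)
      }, numeric(1))
      assign(as.character(sz), nulls, envir = null_by_size)
    }
    rows <- lapply(keep, function(pid) {
      idx <- sort(member_idx[[pid]])
      es <- es_from_hits(idx, absw, N)
      nulls <- get(as.character(length(idx)), envir = null_by_size)
      same <- if (es >= 0) nulls[nulls > 0] else nulls[nulls < 0]
      denom <- mean(abs(same))
      nes <- if (is.finite(denom) && denom > 0) es / denom else 0
      p <- if (es >= 0) {
        (1 + sum(nulls >= es)) / (1 + sum(nulls > 0))
      } else {
        (1 + sum(nulls <= es)) / (1 + sum(nulls < 0))
      }
      data.frame(pathway_id = pid, size = length(idx), es = es, nes = nes,
                 p_raw = min(p, 1), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
    out$direction <- ifelse(out$nes >= 0, "up", "down")
    out <- out[order(out$p_raw, -abs(out$nes)), ]
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
  })
}
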