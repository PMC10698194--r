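# The design funnel: percentile filtering on the metric vector, extracellular
# loop contact filtering, and greedy max-min diversity selection.

#' Metric directionality specification
#'
#' Which side of each metric is favorable. Defaults follow the funnel's three
#' headline metrics: binding energy difference lower-better, shape
#' complementarity and interface area higher-better.
#'
#' @param ... named entries `"lower"` or `"higher"`, e.g.
#'   `metric_spec(ddg = "lower", sc = "higher")`.
#' @return named character vector of class `metric_spec`.
#' @export
metric_spec <- function(...) {
  v <- c(...)
  if (!length(v)) v <- c(ddg = "lower", sc = "higher", interface_area = "higher")
  if (!all(v %in% c("lower", "higher")))
    stop("directions must be 'lower' or 'higher'")
  structure(v, class = "metric_spec")
}

# favorable-side nearest-rank survivors for one metric
.metric_survivors <- function(values, direction, q) {
  n <- length(values)
  f <- if (direction == "higher") values else -values
  k <- ceiling(q * n)
  if (k < 1) return(rep(TRUE, n))
  cutoff <- sort(f)[k]
  f >= cutoff
}

#' Percentile filter on a design metric table
#'
#' A design survives when it lies on the favorable side of the q-quantile
#' (nearest-rank on the favorable ordering, inclusive at ties) for every
#' listed metric. When `target_count` is given and the strict filter is too
#' harsh, q is relaxed jointly on all metrics by binary search until at least
#' `target_count` designs survive.
#'
#' @param table data.frame with an `id` column and the metric columns.
#' @param spec a [metric_spec()].
#' @param q quantile (default 0.90, the funnel's "top 10 percent").
#' @param target_count optional minimum survivor count.
#' @return list of class `filter_result`: `ids`, `survivors` (logical),
#'   `cutoffs` (per metric, on the original scale), `q` (possibly relaxed).
#' @export
percentile_filter <- function(table, spec = metric_spec(), q = 0.90,
                              target_count = NULL) {
  if (!nrow(table)) stop("empty design table")
  miss <- setdiff(names(spec), names(table))
  if (length(miss)) stop("unknown metric(s): ", paste(miss, collapse = ", "))
  for (m in names(spec))
    if (any(!is.finite(table[[m]])))
      stop("missing values in filtered metric: ", m)
  surv_at <- function(qq) {
    s <- rep(TRUE, nrow(table))
    for (m in names(spec))
      s <- s & .metric_survivors(table[[m]], spec[[m]], qq)
    s
  }
  q_used <- q
  s <- surv_at(q)
  if (!is.null(target_count) && sum(s) < target_count) {
    lo <- 0; hi <- q
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (sum(surv_at(mid)) >= target_count) lo <- mid else hi <- mid
    }
    q_used <- lo
    s <- surv_at(q_used)
  }
  cutoffs <- vapply(names(spec), function(m) {
    n <- nrow(table)
    k <- ceiling(q_used * n)
    if (k < 1) return(if (spec[[m]] == "higher") -Inf else Inf)
    f <- if (spec[[m]] == "higher") table[[m]] else -table[[m]]
    cf <- sort(f)[k]
    if (spec[[m]] == "higher") cf else -cf
  }, 0)
  structure(list(ids = table$id[s], survivors = s, cutoffs = cutoffs,
                 q = q_used), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result: %d survivors at q = %.4f\n",
              length(x$ids), x$q))
  for (m in names(x$cutoffs))
    cat(sprintf("  %s cutoff: %.3f\n", m, x$cutoffs[m]))
  invisible(x)
}

#' Extracellular-loop residues contacted by the peptide
#'
#' @param model a `conjugate_model`.
#' @param annotations loop annotation names on the receptor.
#' @param cutoff heavy-atom contact cutoff, Angstrom (inclusive).
#' @return character vector of contacted loop residue keys.
#' @export
loop_contacts <- function(model, annotations = c("ECL2", "ECL3"),
                          cutoff = 4.5) {
  rec <- model$receptor
  for (a in annotations)
    if (!a %in% names(rec$annotations)) stop("missing annotation: ", a)
  at <- model$atoms
  pep <- at$group == "peptide" & toupper(at$element) != "H"
  ra <- rec$atoms
  keys <- residue_key(ra$chain, ra$resno, ra$insert)
  loop_keys <- unique(unlist(rec$annotations[annotations]))
  loop <- keys %in% loop_keys & toupper(ra$element) != "H"
  if (!any(loop) || !any(pep)) return(character())
  A <- as.matrix(at[pep, c("x", "y", "z")])
  B <- as.matrix(ra[loop, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  dmin <- sqrt(pmax(apply(d2, 2, min), 0))
  sort(unique(keys[loop][dmin <= cutoff]))
}

#' Loop-contact filter over a set of conjugate models
#'
#' A design survives when at least one peptide heavy atom lies within the
#' cutoff (inclusive) of at least one heavy atom of the annotated
#' extracellular loops.
#'
#' @param models list of `conjugate_model`s.
#' @param annotations loop annotation names (default ECL2 and ECL3).
#' @param cutoff Angstrom (default 4.5).
#' @return logical vector of survivors.
#' @export
loop_contact_filter <- function(models, annotations = c("ECL2", "ECL3"),
                                cutoff = 4.5) {
  vapply(models, function(m)
    length(loop_contacts(m, annotations, cutoff)) > 0, TRUE)
}

.hamming_frac <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  if (length(av) != length(bv)) return(1)
  mean(av != bv)
}

.jaccard_dist <- function(a, b) {
  if (!length(a) && !length(b)) return(0)
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Greedy max-min diversity selection of the synthesis set
#'
#' Pairwise design distance `d = 0.5 * sequence Hamming fraction +
#' 0.3 * bin-string Hamming fraction + 0.2 * Jaccard distance of
#' loop-contact residue sets`. The first pick is the best (lowest) ddg;
#' subsequent picks greedily maximize the minimum distance to the already
#' selected set. Deterministic (ties broken by table order).
#'
#' @param table data.frame with columns `id`, `ddg`, `sequence` (string),
#'   `bins` (string) and `contacts` (semicolon-joined residue keys, may be
#'   empty).
#' @param k number of designs to select (default 6).
#' @return ids of the selected designs, in pick order.
#' @export
diversity_select <- function(table, k = 6L) {
  if (k <= 0) stop("k must be > 0")
  if (!nrow(table)) stop("empty survivor table")
  n <- nrow(table)
  if (k >= n) return(table$id)
  contacts <- lapply(strsplit(table$contacts, ";", fixed = TRUE),
                     function(v) v[nzchar(v)])
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- 0.5 * .hamming_frac(table$sequence[i], table$sequence[j]) +
         0.3 * .hamming_frac(table$bins[i], table$bins[j]) +
         0.2 * .jaccard_dist(contacts[[i]], contacts[[j]])
    D[i, j] <- D[j, i] <- d
  }
  picked <- which.min(table$ddg)
  while (length(picked) < k) {
    rest <- setdiff(seq_len(n), picked)
    min_d <- apply(D[rest, picked, drop = FALSE], 1, min)
    picked <- c(picked, rest[which.max(min_d)])
  }
  table$id[picked]
}
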