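#' Amplicon count table with taxonomy and sample metadata
#'
#' The container behind all community operations: a samples x ASVs matrix of
#' non-negative integer counts, a taxonomy table mapping every ASV to lineage
#' ranks (unassigned ranks carried as the explicit label `"Unassigned"`), and
#' per-sample metadata (bay, season, depth, site).
#'
#' @param counts Numeric matrix, samples in rows and ASVs in columns, with
#'   dimnames; all entries non-negative integers.
#' @param taxonomy data.frame with column `asv_id` plus one column per rank
#'   (e.g. `domain`, `phylum`, `class`, `order`, `family`), covering every
#'   column of `counts`.
#' @param metadata data.frame with column `sample_id` plus sample covariates
#'   (typically `bay`, `season`, `depth_cm`, `site`), covering every row of
#'   `counts`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, taxonomy, metadata) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must be a matrix with sample rownames and ASV colnames",
         call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("`counts` must be non-negative integers", call. = FALSE)
  stopifnot(is.data.frame(taxonomy), is.data.frame(metadata))
  if (!"asv_id" %in% names(taxonomy))
    stop("`taxonomy` needs an `asv_id` column", call. = FALSE)
  if (!"sample_id" %in% names(metadata))
    stop("`metadata` needs a `sample_id` column", call. = FALSE)
  missing_tax <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(missing_tax))
    stop("taxonomy missing for ASVs: ", paste(utils::head(missing_tax, 5),
                                              collapse = ", "), call. = FALSE)
  missing_meta <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing_meta))
    stop("metadata missing for samples: ", paste(utils::head(missing_meta, 5),
                                                 collapse = ", "), call. = FALSE)
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$asv_id), , drop = FALSE]
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(taxonomy) <- NULL; rownames(metadata) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa (ranks: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(setdiff(names(x$taxonomy), "asv_id"), collapse = ", ")))
  invisible(x)
}

#' Aggregate ASV counts to a taxonomic rank
#'
#' Sums counts over all ASVs sharing the same label at the requested rank;
#' the total count of every sample is conserved. ASVs without an assignment
#' at that rank must already carry an explicit label (e.g. `"Unassigned"`).
#'
#' @param table A [count_table()].
#' @param rank A rank column present in the taxonomy (e.g. `"family"`).
#' @return A [count_table()] whose columns are the rank labels.
#' @export
aggregate_to_rank <- function(table, rank = "family") {
  stopifnot(inherits(table, "count_table"))
  if (!rank %in% setdiff(names(table$taxonomy), "asv_id"))
    stop(sprintf("rank '%s' not present in the taxonomy (have: %s)", rank,
                 paste(setdiff(names(table$taxonomy), "asv_id"), collapse = ", ")),
         call. = FALSE)
  labels <- as.character(table$taxonomy[[rank]])
  labels[is.na(labels) | labels == ""] <- "Unassigned"
  agg <- t(rowsum(t(table$counts), group = labels))
  count_table(agg,
              taxonomy = data.frame(asv_id = colnames(agg),
                                    stats::setNames(list(colnames(agg)), rank),
                                    stringsAsFactors = FALSE),
              metadata = table$metadata)
}

#' Relative abundance with low-abundance pooling
#'
#' Per-sample proportions, optionally keeping only the `top_k` taxa by mean
#' relative abundance across samples (ties broken lexicographically) and
#' pooling the remainder as `"Other_Families"`. Emitted proportions sum to 1
#' in every sample.
#'
#' @param table A [count_table()] (usually already aggregated to a rank).
#' @param top_k Number of taxa to keep (default `Inf`: no pooling).
#' @param other_label Label for the pooled remainder.
#' @return Numeric matrix of proportions, samples x taxa.
#' @export
relative_abundance <- function(table, top_k = Inf, other_label = "Other_Families") {
  stopifnot(inherits(table, "count_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(table$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  props <- table$counts / totals
  if (is.finite(top_k) && top_k < ncol(props)) {
    means <- colMeans(props)
    keep <- colnames(props)[order(-means, colnames(props))][seq_len(top_k)]
    other <- rowSums(props[, !colnames(props) %in% keep, drop = FALSE])
    props <- cbind(props[, keep, drop = FALSE],
                   matrix(other, ncol = 1, dimnames = list(NULL, other_label)))
  }
  props
}

#' Bray-Curtis dissimilarity matrix
#'
#' For two abundance vectors x, y: `d = sum(|x_i - y_i|) / sum(x_i + y_i)`;
#' 0 for identical samples, 1 for samples with disjoint support. Computed on
#' per-sample relative abundances by default so that unequal library sizes do
#' not masquerade as community differences (`relative = FALSE` uses the raw
#' counts).
#'
#' @param x A [count_table()] or a samples x taxa numeric matrix with sample
#'   rownames.
#' @param relative Normalise each sample to proportions first (default
#'   `TRUE`).
#' @return A [stats::dist] object over the samples.
#' @export
bray_curtis <- function(x, relative = TRUE) {
  m <- if (inherits(x, "count_table")) x$counts else x
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("need a matrix with at least 2 sample rows", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("abundances must be finite and non-negative", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("all-zero sample(s): Bray-Curtis undefined for ",
         paste(rownames(m)[tot == 0], collapse = ", "), call. = FALSE)
  if (relative) m <- m / tot
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      num <- sum(abs(m[i, ] - m[j, ]))
      den <- sum(m[i, ] + m[j, ])
      d[i, j] <- d[j, i] <- num / den
    }
  }
  stats::as.dist(structure(d, dimnames = list(rownames(m), rownames(m))))
}

# Gower-centred matrix G = -(1/2) J D^2 J with J = I - 11'/n.
gower_center <- function(d) {
  D <- as.matrix(d)
  if (nrow(D) < 2L) stop("need at least 2 samples", call. = FALSE)
  A <- -0.5 * D^2
  rm_ <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1, rm_), 2, rm_) + gm
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower-centres `-D^2/2`, eigendecomposes, and returns coordinates scaled by
#' the square roots of the positive eigenvalues, axes sorted by decreasing
#' eigenvalue. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but excluded from the
#' coordinates; no Lingoes/Cailliez correction is applied. The proportion
#' explained is relative to the sum of positive eigenvalues.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @return An object of class `smtz_pcoa`: `points` (samples x axes),
#'   `eigenvalues` (all, decreasing), `prop_explained` (positive axes),
#'   `trace` (sum of eigenvalues = trace of the centred matrix).
#' @export
pcoa <- function(d) {
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  vals <- e$values
  tol <- max(abs(vals)) * 1e-8
  pos <- which(vals > tol)
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), length(pos))
  rownames(pts) <- rownames(as.matrix(d))
  colnames(pts) <- paste0("Axis", seq_along(pos))
  structure(list(points = pts, eigenvalues = vals,
                 prop_explained = vals[pos] / sum(vals[pos]),
                 trace = sum(diag(G))),
            class = "smtz_pcoa")
}

#' @export
print.smtz_pcoa <- function(x, ...) {
  cat(sprintf("<pcoa> %d samples, %d positive axes; axis 1-2 explain %.1f%% / %.1f%%; %d negative eigenvalue(s)\n",
              nrow(x$points), ncol(x$points),
              100 * x$prop_explained[1],
              if (length(x$prop_explained) > 1) 100 * x$prop_explained[2] else 0,
              sum(x$eigenvalues < -max(abs(x$eigenvalues)) * 1e-8)))
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix among the terms
#' of a factorial design, using sequential (Type-I) sums of squares computed
#' from the trace of hat-matrix differences applied to the Gower-centred
#' matrix. Pseudo-F per term is `(SS_term/df_term) / (SS_res/df_res)`;
#' significance comes from free permutation of the samples, with
#' `p = (number of permuted F >= observed + 1) / (n_permutations + 1)`.
#'
#' Terms are fitted in the order they appear in the formula, so with
#' unbalanced designs the attribution of shared variation depends on that
#' order; choose it deliberately.
#'
#' @param d A `dist` object or symmetric distance matrix over the samples.
#' @param formula One-sided formula of sample covariates, e.g.
#'   `~ bay * depth_cm + season`.
#' @param data data.frame of covariates, one row per sample in the order of
#'   `d` (e.g. the `metadata` of a [count_table()]).
#' @param permutations Number of permutations (>= 99).
#' @param seed Optional integer seed for reproducible permutations.
#' @return An object of class `permanova`: a data.frame with one row per
#'   term plus `Residual` and `Total` rows, and columns `df`, `sum_sq`,
#'   `pseudo_f`, `r_squared`, `p_value`.
#' @export
permanova <- function(d, formula, data, permutations = 999, seed = NULL) {
  G <- gower_center(d)
  n <- nrow(G)
  stopifnot(is.data.frame(data))
  if (nrow(data) != n)
    stop(sprintf("`data` has %d rows for %d samples", nrow(data), n), call. = FALSE)
  if (permutations < 99) stop("use at least 99 permutations", call. = FALSE)
  trm <- stats::terms(formula)
  labels <- attr(trm, "term.labels")
  if (!length(labels)) stop("formula has no terms", call. = FALSE)
  X <- stats::model.matrix(formula, data)
  asgn <- attr(X, "assign")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  hat_of <- function(cols) {
    if (!length(cols)) return(matrix(0, n, n))
    Q <- qr.Q(qr(X[, cols, drop = FALSE]))
    tcrossprod(Q)
  }
  # sequential projectors: intercept, then cumulative terms
  H_prev <- hat_of(which(asgn == 0L))
  term_proj <- vector("list", length(labels))
  df <- integer(length(labels))
  for (k in seq_along(labels)) {
    H_k <- hat_of(which(asgn <= k))
    term_proj[[k]] <- H_k - H_prev
    df[k] <- sum(asgn == k)
    H_prev <- H_k
  }
  resid_proj <- diag(n) - H_prev
  df_res <- n - qx$rank

  ss_of <- function(Gmat) {
    ss_terms <- vapply(term_proj, function(M) sum(M * Gmat), numeric(1))
    c(ss_terms, sum(resid_proj * Gmat))
  }
  ss <- ss_of(G)
  ss_res <- ss[length(ss)]
  ss_terms <- ss[-length(ss)]
  ss_total <- sum(diag(G))
  f_obs <- (ss_terms / df) / (ss_res / df_res)

  exceed <- rep(0L, length(labels))
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      p <- sample.int(n)
      ssp <- ss_of(G[p, p])
      fp <- (ssp[-length(ssp)] / df) / (ssp[length(ssp)] / df_res)
      exceed <- exceed + (fp >= f_obs)
    }
  })
  p_val <- (exceed + 1) / (permutations + 1)

  out <- data.frame(
    term = c(labels, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    sum_sq = c(ss_terms, ss_res, ss_total),
    pseudo_f = c(f_obs, NA_real_, NA_real_),
    r_squared = c(ss_terms, ss_res, ss_total) / ss_total,
    p_value = c(p_val, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  structure(out, class = c("permanova", "data.frame"),
            n_permutations = permutations, seed = seed)
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d free permutations)\n",
              attr(x, "n_permutations")))
  df <- as.data.frame(x)
  df$sum_sq <- signif(df$sum_sq, 5)
  df$pseudo_f <- signif(df$pseudo_f, 4)
  df$r_squared <- round(df$r_squared, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
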