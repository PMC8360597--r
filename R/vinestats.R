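# Task-responsiveness of a vine: Wasserstein group statistic on
# vine-stripped diagrams, with block-respecting label permutation.
#
# The statistic is the joint within-group loss
#   S = sum over the two groups of mean over unordered within-group pairs of
#       W_q(D_i, D_j)^q,
# where W_q is the exact q-Wasserstein distance between single-dimension
# persistence diagrams (sup-norm ground metric, unmatched points pay their
# distance to the diagonal).  Small S means tight within-group cohesion, so
# the p-value counts permuted statistics <= the observed one.  Labels are
# permuted at the whole-block level of the two tested conditions only,
# preserving within-block temporal autocorrelation.

#' Task design of a block experiment
#'
#' @param labels character vector, one condition label per time index; blocks
#'   are the maximal contiguous runs of equal labels.
#' @return an object of class `task_design` with fields `labels` and `blocks`
#'   (data frame `condition`, `start`, `end`, 1-based positions partitioning
#'   the index range).
#' @export
task_design <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("design needs at least one time index")
  r <- rle(labels)
  end <- cumsum(r$lengths)
  structure(list(labels = labels,
                 blocks = data.frame(condition = r$values,
                                     start = end - r$lengths + 1L,
                                     end = end)),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %d time indices, %d blocks (%s)\n",
              length(x$labels), nrow(x$blocks),
              paste(unique(x$blocks$condition), collapse = ", ")))
  invisible(x)
}

#' Read a task design from a delimited file
#'
#' Either long form with columns `t, condition` (one row per time index,
#' sorted by `t`) or compact block form with columns `condition, length`
#' (blocks in order, expanded to per-index labels).
#'
#' @param path a delimited text file.
#' @return a [task_design()].
#' @export
read_design <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("t", "condition") %in% names(tab))) {
    task_design(tab$condition[order(tab$t)])
  } else if (all(c("condition", "length") %in% names(tab))) {
    task_design(rep(tab$condition, tab$length))
  } else {
    stop("design file needs columns (t, condition) or (condition, length)")
  }
}

# (birth, death) matrix of one homology dimension, truncated deaths -> r_max
diagram_matrix <- function(d, dim = 1L, r_max = NULL) {
  if (inherits(d, "persistence_diagram")) {
    f <- d$features[d$features$dim == dim, , drop = FALSE]
    rm <- if (is.null(r_max)) d$r_max else r_max
    cbind(f$birth, ifelse(f$truncated, rm, f$death))
  } else {
    m <- as.matrix(d)
    if (length(m) == 0L) matrix(numeric(), 0L, 2L) else {
      if (ncol(m) != 2L) stop("a plain diagram must be a 2-column matrix")
      if (anyNA(m[, 2]) && is.null(r_max))
        stop("truncated deaths need r_max")
      m[, 2][is.na(m[, 2])] <- r_max
      m
    }
  }
}

#' Wasserstein distance between persistence diagrams
#'
#' The exact q-Wasserstein distance restricted to one homology dimension:
#' the minimum over partial matchings of `(sum of cost^q)^(1/q)`, where a
#' matched pair pays its sup-norm distance and an unmatched point pays its
#' sup-norm distance to the diagonal, `(death - birth) / 2`.  Computed by
#' optimal assignment on the diagonal-augmented cost matrix.  Truncated
#' deaths are replaced by `r_max` first.  Sensitive to both persistence
#' changes and feature presence/absence; two empty diagrams are at distance
#' 0.
#'
#' @param d1,d2 `persistence_diagram`s, or plain 2-column (birth, death)
#'   matrices.
#' @param q order, `>= 1`; default 2.
#' @param dim homology dimension to compare (default 1).
#' @param r_max replacement death for truncated classes; defaults to the
#'   diagrams' own `r_max`.
#' @return the distance, a nonnegative number.
#' @examples
#' wasserstein_distance(rbind(c(0, 2)), rbind(c(0, 4)), q = 1)  # 2
#' @export
wasserstein_distance <- function(d1, d2, q = 2, dim = 1L, r_max = NULL) {
  if (!is.numeric(q) || q < 1) stop("q must be >= 1")
  m1 <- diagram_matrix(d1, dim, r_max)
  m2 <- diagram_matrix(d2, dim, r_max)
  wasserstein_cost(m1, m2, q)^(1 / q)
}

# total matched cost^q between two (birth, death) matrices
wasserstein_cost <- function(m1, m2, q) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  if (n1 + n2 == 0L) return(0)
  diag1 <- (m1[, 2] - m1[, 1]) / 2
  diag2 <- (m2[, 2] - m2[, 1]) / 2
  if (n1 == 0L) return(sum(diag2^q))
  if (n2 == 0L) return(sum(diag1^q))
  pp <- matrix(0, n1, n2)  # sup-norm point-to-point costs
  for (i in seq_len(n1))
    pp[i, ] <- pmax(abs(m1[i, 1] - m2[, 1]), abs(m1[i, 2] - m2[, 2]))
  big <- sum(pp^q) + sum(diag1^q) + sum(diag2^q) + 1
  N <- n1 + n2
  C <- matrix(0, N, N)
  C[seq_len(n1), seq_len(n2)] <- pp^q
  C[seq_len(n1), n2 + seq_len(n1)] <- big
  C[cbind(seq_len(n1), n2 + seq_len(n1))] <- diag1^q
  C[n1 + seq_len(n2), seq_len(n2)] <- big
  C[cbind(n1 + seq_len(n2), seq_len(n2))] <- diag2^q
  cpp_assignment_cost(C)
}

#' Within-group cohesion statistic
#'
#' `S = sum over the two groups of [mean over unordered within-group pairs
#' of W_q(D_i, D_j)^q]`.  Small S indicates label-aligned structure.
#'
#' @param diagrams list of diagrams (one per time index in the comparison).
#' @param labels vector of exactly two distinct values, aligned with
#'   `diagrams`; each group needs at least 2 members.
#' @inheritParams wasserstein_distance
#' @return the statistic, a nonnegative number.
#' @export
group_statistic <- function(diagrams, labels, q = 2, dim = 1L, r_max = NULL) {
  W <- pairwise_wasserstein_power(diagrams, q, dim, r_max)
  statistic_from_matrix(W, labels)
}

pairwise_wasserstein_power <- function(diagrams, q, dim = 1L, r_max = NULL) {
  mats <- lapply(diagrams, diagram_matrix, dim = dim, r_max = r_max)
  n <- length(mats)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      W[i, j] <- W[j, i] <- wasserstein_cost(mats[[i]], mats[[j]], q)
  W
}

statistic_from_matrix <- function(Wq, labels) {
  groups <- unique(labels)
  if (length(groups) != 2L)
    stop("exactly two label values are required, got ", length(groups))
  s <- 0
  for (g in groups) {
    idx <- which(labels == g)
    if (length(idx) < 2L) stop("group '", g, "' has fewer than 2 diagrams")
    sub <- Wq[idx, idx]
    s <- s + sum(sub[upper.tri(sub)]) / choose(length(idx), 2L)
  }
  s
}

#' Permute condition labels at the block level
#'
#' The condition assignments of the blocks belonging to the two tested
#' conditions are permuted uniformly at random at the whole-block level;
#' time indices keep their block membership and all other conditions are
#' untouched.  This respects the temporal structure of the task: within-block
#' autocorrelation is never broken.
#'
#' @param design a [task_design()].
#' @param conditions the two condition names under test.
#' @return a character vector of permuted labels, same length as
#'   `design$labels`.
#' @export
permute_labels_blockwise <- function(design, conditions) {
  stopifnot(inherits(design, "task_design"), length(conditions) == 2L)
  b <- design$blocks
  sel <- which(b$condition %in% conditions)
  for (cond in conditions)
    if (sum(b$condition == cond) < 2L)
      stop("need at least 2 blocks of condition '", cond, "'")
  perm <- sample(b$condition[sel])
  labels <- design$labels
  for (k in seq_along(sel))
    labels[b$start[sel[k]]:b$end[sel[k]]] <- perm[k]
  labels
}

#' Block-permutation Wasserstein test of task-responsiveness
#'
#' Tests the null hypothesis that the label assignments based on condition
#' produce two groups of diagrams no more distinct than if labels were
#' chosen at random.  The observed within-group cohesion statistic is
#' compared against its distribution under block-level label permutation,
#' with the plus-one Monte-Carlo estimator
#' `p = (1 + #\{S_perm <= S_obs\}) / (1 + n_perm)`.  Empty diagrams
#' participate through the all-to-diagonal matching, so intermittent presence
#' of the vine itself carries signal.
#'
#' @param x a [extract_vine()] selection (or a list of diagrams, one per
#'   time index of the design).
#' @param design a [task_design()] whose length matches `x`.
#' @param conditions the two compared conditions; default
#'   `c("encoding", "retrieval")`.
#' @param n_perm number of permutations, `>= 99`; default 4999.
#' @param q Wasserstein order; default 2.
#' @param dim homology dimension; default 1.
#' @param seed RNG seed (always recorded in the result); default 0.
#' @param r_max see [wasserstein_distance()].
#' @return an object of class `vine_test`: observed statistic, null sample,
#'   p-value, permutation count, seed and group labels.
#' @export
vine_permutation_test <- function(x, design, conditions = c("encoding", "retrieval"),
                                  n_perm = 4999, q = 2, dim = 1L, seed = 0,
                                  r_max = NULL) {
  diagrams <- if (inherits(x, "vine_selection")) x$diagrams else x
  stopifnot(inherits(design, "task_design"))
  if (length(diagrams) != length(design$labels))
    stop("design length (", length(design$labels),
         ") does not match the number of diagrams (", length(diagrams), ")")
  if (n_perm < 99) stop("n_perm must be >= 99")
  keep <- which(design$labels %in% conditions)
  if (!length(keep)) stop("no time indices carry the tested conditions")
  W <- pairwise_wasserstein_power(diagrams[keep], q, dim, r_max)
  observed <- statistic_from_matrix(W, design$labels[keep])

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    lab <- permute_labels_blockwise(design, conditions)
    statistic_from_matrix(W, lab[keep])
  }, numeric(1))
  p <- (1 + sum(null_stats <= observed)) / (1 + n_perm)
  structure(list(statistic = observed, null_statistics = null_stats,
                 p.value = p, n_permutations = as.integer(n_perm),
                 seed = seed, group_labels = conditions, q = q, dim = dim),
            class = "vine_test")
}

#' @export
print.vine_test <- function(x, ...) {
  cat("\tBlock-permutation Wasserstein test of vine task-responsiveness\n\n")
  cat(sprintf("groups: %s vs %s (H%d, q = %g)\n",
              x$group_labels[1], x$group_labels[2], x$dim, x$q))
  cat(sprintf("S_observed = %.6g, n_perm = %d, seed = %s\n",
              x$statistic, x$n_permutations, format(x$seed)))
  cat(sprintf("p = %.4g\n", x$p.value))
  invisible(x)
}

#' @export
plot.vine_test <- function(x, ...) {
  graphics::hist(x$null_statistics, breaks = 40,
                 main = "Null distribution of S", xlab = "S")
  graphics::abline(v = x$statistic, col = "red", lwd = 2)
  invisible(x)
}
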