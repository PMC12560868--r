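#' Neighbor-joining tree
#'
#' Canonical neighbor joining on a dissimilarity matrix: at each step the
#' pair minimizing \eqn{Q_{ij} = (m-2) d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}}
#' is joined (ties broken by lexicographic pair order in the current matrix),
#' with the standard branch-length formulas. Negative branch-length
#' estimates are clamped to zero and flagged via the `negative_clamped`
#' attribute. On additive distances NJ recovers the generating topology and
#' path lengths exactly.
#'
#' @param dist a symmetric dissimilarity matrix with row/column names (a
#'   `square_matrix`, plain matrix, or `dist`).
#' @return An [ape::read.tree()]-style `phylo` object (unrooted for 4+
#'   leaves); fewer than 3 leaves returns a trivial tree with a warning.
#' @export
nj_tree <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- labs
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix is not symmetric")

  clamped <- FALSE
  bl <- function(b) {
    if (b < 0) clamped <<- TRUE
    max(0, b)
  }
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

  # The tree is assembled over placeholder labels (safe for any character
  # set) and the true labels are restored on the parsed object.
  ph <- paste0("T", seq_len(n))
  restore <- function(tree) {
    tree$tip.label <- labs[match(tree$tip.label, ph)]
    tree
  }

  if (n < 3L) {
    warning("fewer than 3 leaves; returning trivial tree")
    nwk <- if (n == 1L) paste0("(", ph[1], ":0);") else
      paste0("(", ph[1], ":", fmt(D[1, 2] / 2), ",",
             ph[2], ":", fmt(D[1, 2] / 2), ");")
    tree <- restore(ape::read.tree(text = nwk))
    attr(tree, "negative_clamped") <- FALSE
    return(tree)
  }

  # Active nodes carry their partial Newick representation.
  rep_nwk <- ph
  m <- n
  while (m > 3L) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    cand <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]

    bi <- bl(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- bl(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_rep <- paste0("(", rep_nwk[i], ":", fmt(bi), ",",
                      rep_nwk[j], ":", fmt(bj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    rep_nwk <- c(rep_nwk[keep], new_rep)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
    m <- m - 1L
  }
  b1 <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", rep_nwk[1], ":", fmt(b1), ",", rep_nwk[2], ":",
                fmt(b2), ",", rep_nwk[3], ":", fmt(b3), ");")
  tree <- restore(ape::read.tree(text = nwk))
  attr(tree, "negative_clamped") <- clamped
  tree
}

#' Serialize a tree to Newick
#'
#' Standard Newick with branch lengths, terminated by `";"`; spaces in
#' labels are written as underscores per the Newick unquoted-label
#' convention.
#'
#' @param tree a `phylo` object.
#' @return A single Newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Kinship-threshold family assignment
#'
#' Core families are the connected components of the graph over bulls with
#' edges where genomic kinship is at least `threshold` (singleton bulls form
#' singleton families), numbered by the order of their lowest-id bull. Each
#' cow joins the family containing the bull she is most related to, provided
#' that maximum kinship reaches the threshold; otherwise she is classed in
#' `other_cows`. When a cow exceeds the threshold with bulls of several
#' families, the single highest-kinship bull decides (ties by bull id).
#'
#' @param g a kinship `square_matrix` (kind `"grm"`) covering all
#'   individuals.
#' @param samples sample sheet with `iid` and `sex` columns.
#' @param threshold kinship threshold.
#' @param exclude_ids ids (e.g. outlier bulls) dropped before assignment.
#' @return An object of class `family_assignment`: `families` (list of
#'   `list(bulls, cows)`), `other_cows`, `threshold`, `membership` (named
#'   vector: family label or `"other"` per individual).
#' @export
assign_families <- function(g, samples, threshold = 0.1,
                            exclude_ids = character(0)) {
  ids <- samples$iid[!(samples$iid %in% exclude_ids)]
  if (!all(ids %in% rownames(g))) stop("kinship matrix must cover all ids")
  sex <- stats::setNames(samples$sex, samples$iid)[ids]
  bulls <- sort(ids[sex == "male"])
  cows <- ids[sex != "male"]
  if (!length(bulls)) {
    warning("no bulls; every cow classed as other")
    memb <- stats::setNames(rep("other", length(cows)), cows)
    return(structure(list(families = list(), other_cows = cows,
                          threshold = threshold, membership = memb),
                     class = "family_assignment"))
  }

  # Connected components of the >= threshold graph over bulls.
  adj <- g[bulls, bulls, drop = FALSE] >= threshold
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, length(bulls))
  cid <- 0L
  for (b in seq_along(bulls)) {
    if (!is.na(comp[b])) next
    cid <- cid + 1L
    queue <- b
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cid
      queue <- c(queue, which(adj[cur, ] & is.na(comp)))
    }
  }
  # Families ordered by their lowest-id bull (bulls already sorted).
  order_key <- vapply(seq_len(cid), function(k) min(bulls[comp == k]),
                      character(1))
  ord <- order(order_key)
  families <- lapply(ord, function(k) {
    list(bulls = bulls[comp == k], cows = character(0))
  })
  fam_of_comp <- match(seq_len(cid), ord)   # component id -> family index

  other_cows <- character(0)
  memb <- stats::setNames(character(length(ids)), ids)
  for (k in seq_along(families)) memb[families[[k]]$bulls] <- paste0("F", k)
  for (cw in cows) {
    kin <- g[cw, bulls]
    best <- which(kin == max(kin))[1]          # ties: first = smallest id
    if (kin[best] >= threshold) {
      k <- fam_of_comp[comp[best]]
      families[[k]]$cows <- c(families[[k]]$cows, cw)
      memb[cw] <- paste0("F", k)
    } else {
      other_cows <- c(other_cows, cw)
      memb[cw] <- "other"
    }
  }
  structure(list(families = families, other_cows = other_cows,
                 threshold = threshold, membership = memb),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("family_assignment:", length(x$families), "families, threshold",
      x$threshold, "\n")
  for (k in seq_along(x$families)) {
    f <- x$families[[k]]
    cat(sprintf("  F%d: %d bull(s), %d cow(s)\n", k, length(f$bulls),
                length(f$cows)))
  }
  cat("  other:", length(x$other_cows), "cow(s)\n")
  invisible(x)
}
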