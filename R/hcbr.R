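# Hypergraph case-based reasoning (HCBR) binary classifier.
#
# A feature vector becomes a "case": the set of (feature index, rounded
# value) tokens. Cases are hyperedges over the token universe; tokens with
# identical case-membership signatures form the cells of the partition (the
# intersection family, or "tribe"). The model is s = W mu, where row j of W
# holds the fraction of case j's tokens falling in each cell (||w_j||_1 = 1)
# and mu is a signed per-cell intrinsic strength with ||mu||_1 = 1.
# Prediction projects a query case onto the partition and takes the sign of
# its support, a convex combination of mu.

#' Discretize a numeric vector into an HCBR case
#'
#' Tokens are `"<index>:<value rounded to digits decimals>"`; rounding makes
#' nearly equal feature values collide so that cases can intersect.
#'
#' @param x Numeric vector with finite entries.
#' @param digits Decimal digits kept (the canonical pipeline uses 4).
#' @param label Optional class label carried along.
#' @return An object of class `hcbr_case` with `elements` (character set)
#'   and `label`.
#' @export
hcbr_discretize <- function(x, digits = 4L, label = NA_character_) {
  if (any(!is.finite(x))) {
    stop_p300("non-finite entry at position %d", which(!is.finite(x))[1L],
              class = "value_error")
  }
  digits <- assert_count(digits, "digits", min = 0L)
  v <- round(x, digits) + 0              # + 0 collapses IEEE negative zero
  elements <- sprintf("%d:%.*f", seq_along(x), digits, v)
  structure(list(elements = elements, label = label), class = "hcbr_case")
}

#' Partition the token universe of a set of cases
#'
#' Two tokens share a cell iff they occur in exactly the same set of cases
#' (identical membership signature). The cells are pairwise disjoint and
#' cover every observed token; the construction is invariant to case order.
#'
#' @param cases List of `hcbr_case` objects (each non-empty).
#' @return List of cells, each a character vector of tokens, ordered by
#'   first token occurrence.
#' @export
hcbr_partition <- function(cases) {
  if (length(cases) == 0L) {
    stop_p300("need at least one case", class = "structure_error")
  }
  sizes <- vapply(cases, function(cs) length(cs$elements), 0L)
  if (any(sizes == 0L)) {
    stop_p300("case %d is empty", which(sizes == 0L)[1L],
              class = "structure_error")
  }
  tokens <- unique(unlist(lapply(cases, `[[`, "elements")))
  sig <- vapply(tokens, function(tk) {
    paste(which(vapply(cases, function(cs) tk %in% cs$elements, TRUE)),
          collapse = ",")
  }, "")
  unname(split(tokens, factor(sig, levels = unique(sig))))
}

#' Fit the HCBR model
#'
#' Builds the partition and the importance matrix
#' `W[j, i] = |cell_i intersect case_j| / |case_j|`, initializes the signed
#' strength `mu` from the overlap-weighted class balance of the cases
#' meeting each cell, normalizes `||mu||_1 = 1`, then runs `l0` correction
#' passes: every training case misclassified by `sign(W mu)` shifts `mu`
#' mass toward its true class along its own W row with step `eta`,
#' renormalizing after each pass.
#'
#' @param cases List of `hcbr_case` objects.
#' @param labels Per-case class labels; exactly two classes must be present.
#'   The lexicographically second class is the positive (support > 0)
#'   class, so the fit is invariant to case order.
#' @param l0 Number of correction passes (the canonical setting is 1).
#' @param eta Correction step size.
#' @return An object of class `hcbr_model`.
#' @export
hcbr_fit <- function(cases, labels, l0 = 1L, eta = 0.1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop_p300("HCBR is a binary classifier; got %d class(es)", length(classes),
              class = "class_error")
  }
  l0 <- assert_count(l0, "l0", min = 0L)
  y <- ifelse(labels == classes[2L], 1, -1)
  partition <- hcbr_partition(cases)
  m <- length(partition)
  n <- length(cases)
  cell_of <- rep(seq_len(m), lengths(partition))
  names(cell_of) <- unlist(partition)
  w <- matrix(0, nrow = n, ncol = m)
  for (j in seq_len(n)) {
    cells <- cell_of[cases[[j]]$elements]
    tab <- tabulate(cells, nbins = m)
    w[j, ] <- tab / length(cases[[j]]$elements)
  }
  mu <- as.vector(crossprod(w, y))         # overlap-weighted class balance
  if (sum(abs(mu)) == 0) mu <- rep(1 / m, m) else mu <- mu / sum(abs(mu))
  for (pass in seq_len(l0)) {
    s <- as.vector(w %*% mu)
    # zero support counts as misclassified; the 1e-12 band keeps the wrong
    # set independent of floating-point summation order
    wrong <- which(sign(s) != y | abs(s) < 1e-12)
    for (j in wrong) mu <- mu + eta * y[j] * w[j, ]
    mu <- mu / sum(abs(mu))
  }
  tabcls <- table(factor(labels, levels = classes))
  structure(list(partition = partition, cell_of = cell_of, W = w, mu = mu,
                 classes = classes,
                 default_class = classes[which.max(tabcls)],
                 l0 = l0, eta = eta),
            class = "hcbr_model")
}

#' Predict with an HCBR model
#'
#' The query's support is `sum_i (|cell_i intersect case| / |case|) * mu_i`
#' over the cells it intersects; the predicted class is the sign of the
#' support (positive = second training class). A query sharing no token
#' with the hypergraph cannot be decided: the majority training class is
#' returned with support 0 and `abstained = TRUE`.
#'
#' @param model An `hcbr_model`.
#' @param case An `hcbr_case` (or a list of them, returning a data.frame).
#' @return List with `class`, `support`, `abstained` (or a data.frame for a
#'   list input).
#' @export
hcbr_predict <- function(model, case) {
  if (!inherits(case, "hcbr_case") && is.list(case)) {
    res <- lapply(case, function(cs) hcbr_predict(model, cs))
    return(data.frame(class = vapply(res, `[[`, "", "class"),
                      support = vapply(res, `[[`, 0, "support"),
                      abstained = vapply(res, `[[`, TRUE, "abstained")))
  }
  hit <- model$cell_of[intersect(case$elements, names(model$cell_of))]
  if (length(hit) == 0L) {
    return(list(class = model$default_class, support = 0, abstained = TRUE))
  }
  weights <- tabulate(hit, nbins = length(model$mu)) / length(case$elements)
  support <- sum(weights * model$mu)
  cls <- if (support > 0) model$classes[2L]
         else if (support < 0) model$classes[1L]
         else model$default_class
  list(class = cls, support = support, abstained = FALSE)
}
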