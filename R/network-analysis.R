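#' Extract the three symptom networks from a fitted panel GVAR
#'
#' The temporal network is the estimated lag-1 matrix beta (entry
#' \code{[j, i]}: item i at session t-1 predicting item j at session t);
#' the contemporaneous and between-person networks are the two partial
#' correlation matrices. Significance masks come from Wald tests at
#' \code{alpha}. The autoregressive diagonal is retained in the temporal
#' matrix but flagged separately (\code{autoregressive}), since network
#' visualisation and centrality conventionally omit self-loops.
#'
#' @param model A \code{panel_gvar_fit}; if inference is missing it is
#'   computed via [edge_inference()].
#' @param alpha Significance level for the masks.
#' @return A list of class \code{network_set}: \code{temporal},
#'   \code{contemporaneous}, \code{between}, \code{masks} (same-shape
#'   logical matrices), \code{autoregressive} (named vector), and
#'   \code{alpha}.
#' @export
extract_networks <- function(model, alpha = 1e-4) {
  if (is.null(model$pvalues) || !identical(model$alpha, alpha)) {
    model <- edge_inference(model, alpha = alpha)
  }
  temporal <- model$params$beta
  dimnames(temporal) <- list(model$items, model$items)
  contemporaneous <- model$params$omega_zeta
  dimnames(contemporaneous) <- list(model$items, model$items)
  between <- model$params$omega_between
  dimnames(between) <- list(model$items, model$items)
  as_mask <- function(p) {
    s <- !is.na(p) & p < alpha
    dim(s) <- dim(p); dimnames(s) <- list(model$items, model$items)
    s
  }
  structure(list(
    temporal = temporal,
    contemporaneous = contemporaneous,
    between = between,
    masks = list(temporal = as_mask(model$pvalues$beta),
                 contemporaneous = as_mask(model$pvalues$omega_zeta),
                 between = as_mask(model$pvalues$omega_between)),
    autoregressive = stats::setNames(diag(temporal), model$items),
    alpha = alpha), class = "network_set")
}

#' Expected Influence centrality
#'
#' Expected Influence (EI) is the sum of an item's signed edge weights,
#' excluding the self-loop. For the directed temporal network, In-EI of
#' item j sums the incoming effects \code{temporal[j, i]} over i != j and
#' Out-EI of item i sums the outgoing effects \code{temporal[j, i]} over
#' j != i; undirected networks get a single EI per item. Each EI column
#' is also z-standardised across items (reported as 0, with
#' \code{degenerate} flagged, when a column is constant).
#'
#' @param net A \code{network_set}.
#' @return Data frame with one row per item: \code{in_ei},
#'   \code{out_ei}, \code{ei_contemporaneous}, \code{ei_between}, and
#'   their \code{z_} versions.
#' @export
expected_influence <- function(net) {
  tm <- net$temporal
  off <- tm
  diag(off) <- 0
  in_ei <- rowSums(off)
  out_ei <- colSums(off)
  und_ei <- function(M) { diag(M) <- 0; rowSums(M) }
  tab <- data.frame(item = rownames(tm),
                    in_ei = in_ei, out_ei = out_ei,
                    ei_contemporaneous = und_ei(net$contemporaneous),
                    ei_between = und_ei(net$between),
                    row.names = NULL)
  degenerate <- character(0)
  for (col in c("in_ei", "out_ei", "ei_contemporaneous", "ei_between")) {
    s <- stats::sd(tab[[col]])
    if (!is.finite(s) || s == 0) {
      tab[[paste0("z_", col)]] <- 0
      degenerate <- c(degenerate, col)
    } else {
      tab[[paste0("z_", col)]] <- (tab[[col]] - mean(tab[[col]])) / s
    }
  }
  attr(tab, "degenerate") <- degenerate
  tab
}

#' Network density: sum of absolute edge weights
#'
#' Sums \code{|weight|} over unique edges — the upper triangle for an
#' undirected network, all off-diagonal entries for a directed one.
#' Absolute weights are used so that positive and negative edges cannot
#' cancel; \code{signed = TRUE} restores the literal signed sum.
#'
#' @param adjacency Weighted square matrix.
#' @param directed Is the network directed?
#' @param signed Sum signed weights instead of absolute weights.
#' @return Scalar density.
#' @export
network_density <- function(adjacency, directed = FALSE, signed = FALSE) {
  stopifnot(is_square(adjacency))
  w <- if (directed) {
    adjacency[row(adjacency) != col(adjacency)]
  } else {
    adjacency[upper.tri(adjacency)]
  }
  sum(if (signed) w else abs(w))
}

#' Rank agreement between two networks
#'
#' Spearman correlation over the vectorised unique-edge entries (upper
#' triangle if undirected, all off-diagonal if directed). Constant edge
#' vectors make the correlation undefined; \code{NA} is returned with a
#' warning.
#'
#' @param a,b Same-shape weighted matrices.
#' @param directed Are the networks directed?
#' @return Spearman correlation (scalar, possibly \code{NA}).
#' @export
compare_networks <- function(a, b, directed = FALSE) {
  stopifnot(is_square(a), all(dim(a) == dim(b)))
  pick <- if (directed) row(a) != col(a) else upper.tri(a)
  va <- a[pick]; vb <- b[pick]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("constant edge vector; rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb, method = "spearman")
}

#' Edge list of a network
#'
#' @param weights Weighted matrix.
#' @param mask Optional same-shape significance mask.
#' @param pvalues Optional same-shape p-value matrix.
#' @param directed Directed network? Undirected networks list each edge
#'   once (upper triangle).
#' @return Data frame \code{from}, \code{to}, \code{weight}, \code{p},
#'   \code{significant}. For a directed network \code{from} is the
#'   predictor at the earlier session.
#' @export
network_edge_list <- function(weights, mask = NULL, pvalues = NULL,
                              directed = FALSE) {
  nm <- rownames(weights) %||% as.character(seq_len(nrow(weights)))
  pick <- which(if (directed) row(weights) != col(weights) else upper.tri(weights),
                arr.ind = TRUE)
  data.frame(
    from = nm[pick[, if (directed) "col" else "row"]],
    to = nm[pick[, if (directed) "row" else "col"]],
    weight = weights[pick],
    p = if (is.null(pvalues)) NA_real_ else pvalues[pick],
    significant = if (is.null(mask)) NA else mask[pick])
}
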