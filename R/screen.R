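# Library screening and hit triage: Tanimoto similarity network, 2-D
# chemical-space embedding (reporting only), and the probability /
# neighbor-count / property filters.

#' Build a structural-similarity network
#'
#' Nodes are molecules; an undirected edge joins two distinct molecules
#' whose fingerprint Tanimoto similarity meets the edge threshold. The
#' neighbor count used in hit triage is the node degree.
#'
#' @param library molecule records (canonicalized, deduplicated).
#' @param edge_threshold Tanimoto similarity in `[0, 1]` (default 0.4).
#' @param fp optional precomputed binary fingerprint matrix (rows aligned
#'   with `library`); computed from ECFP4 bits when `NULL`.
#' @return object of class `similarity_network`: list with `graph` (an
#'   igraph object), `neighbor_count` (named vector), `edges` (data.frame
#'   id1/id2/similarity), `edge_threshold`.
#' @export
build_similarity_network <- function(library, edge_threshold = 0.4,
                                     fp = NULL) {
  stopifnot(edge_threshold >= 0, edge_threshold <= 1)
  ids <- if (is.data.frame(library)) library$id else
    paste0("mol_", seq_along(library))
  n <- length(ids)
  if (n == 0) {
    return(structure(list(graph = igraph::make_empty_graph(0),
                          neighbor_count = setNames(integer(0), character(0)),
                          edges = data.frame(id1 = character(0),
                                             id2 = character(0),
                                             similarity = numeric(0)),
                          edge_threshold = edge_threshold),
                     class = "similarity_network"))
  }
  if (is.null(fp)) {
    smiles <- if (is.data.frame(library)) library$smiles else library
    fp <- ecfp_fingerprint(smiles)
  }
  sim <- tanimoto(fp)
  adj <- sim >= edge_threshold
  diag(adj) <- FALSE
  up <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(id1 = ids[up[, 1]], id2 = ids[up[, 2]],
                      similarity = sim[up], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = ids))
  deg <- igraph::degree(g)
  deg <- setNames(as.integer(deg), names(deg))
  structure(list(graph = g, neighbor_count = deg[ids], edges = edges,
                 edge_threshold = edge_threshold),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("similarity_network: %d nodes, %d edges (Tanimoto >= %.2f)\n",
              length(x$neighbor_count), nrow(x$edges), x$edge_threshold))
  invisible(x)
}

#' 2-D chemical-space embedding (t-SNE)
#'
#' Exact t-distributed stochastic neighbor embedding of a feature matrix:
#' Gaussian input affinities calibrated per point to the target perplexity
#' by bisection, Student-t output affinities, gradient descent with early
#' exaggeration and momentum. Coordinates are for visual triage maps only
#' and are never used for filtering.
#'
#' @param features numeric matrix (n x d), n >= 3.
#' @param perplexity effective neighborhood size; must be `< n` (default
#'   30, capped at `(n - 1) / 3`).
#' @param rng_seed integer seed (deterministic layout).
#' @param max_iter gradient iterations (default 400).
#' @return n x 2 coordinate matrix (rownames preserved).
#' @export
embed_2d <- function(features, perplexity = 30, rng_seed = 1L,
                     max_iter = 400L) {
  n <- nrow(features)
  if (is.null(n) || n < 3) stop("embedding needs at least 3 molecules")
  if (perplexity >= n) stop("perplexity must be smaller than n")
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(features))^2
  p <- .tsne_affinities(d2, perplexity)
  set.seed(rng_seed)
  y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  .tsne_descent(p, y, max_iter = max_iter)
}

# row-wise bisection for precision beta st perplexity(P_i) = target
.tsne_affinities <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.eps) sw <- .Machine$double.eps
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else { hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- w / sum(w)
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

.tsne_descent <- function(p, y, max_iter = 400L, momentum0 = 0.5,
                          momentum1 = 0.8, eta = 100, exaggeration = 4,
                          stop_exaggeration = 100L) {
  n <- nrow(y)
  vel <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  pe <- p * exaggeration
  for (iter in seq_len(max_iter)) {
    pp <- if (iter <= stop_exaggeration) pe else p
    d2 <- as.matrix(stats::dist(y))^2
    num <- 1 / (1 + d2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (pp - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    mom <- if (iter < 250) momentum0 else momentum1
    gains <- ifelse(sign(grad) != sign(vel), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    vel <- mom * vel - eta * gains * grad
    y <- y + vel
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

#' Hit-filter criteria
#'
#' Defaults follow the screening protocol: class probability in the 0.6 to
#' 0.9 band (the upper bound excludes molecules so close to the training
#' actives that they are unlikely to be novel off-target chemistry; raise
#' `prob_max` to 1 to keep them), at least `min_neighbors` similarity-
#' network neighbors, and drug-likeness property windows (HBA 0-10,
#' HBD 0-5, cLogP 0-5, molecular weight 300-1000 g/mol).
#'
#' @param prob_min,prob_max class-probability band (inclusive).
#' @param min_neighbors minimum similarity-network degree (inclusive).
#' @param hba_range,hbd_range,clogp_range,mw_range inclusive property
#'   windows.
#' @return list of class `hit_criteria`.
#' @export
hit_criteria <- function(prob_min = 0.6, prob_max = 0.9, min_neighbors = 3L,
                         hba_range = c(0, 10), hbd_range = c(0, 5),
                         clogp_range = c(0, 5), mw_range = c(300, 1000)) {
  for (r in list(hba_range, hbd_range, clogp_range, mw_range,
                 c(prob_min, prob_max)))
    stopifnot(length(r) == 2, r[1] <= r[2])
  structure(list(prob_min = prob_min, prob_max = prob_max,
                 min_neighbors = as.integer(min_neighbors),
                 hba_range = hba_range, hbd_range = hbd_range,
                 clogp_range = clogp_range, mw_range = mw_range),
            class = "hit_criteria")
}

#' Assemble per-molecule screening records
#'
#' @param library molecule records.
#' @param probability class-1 probabilities aligned with `library` (NA
#'   allowed; such molecules are flagged, never silently dropped).
#' @param network a [build_similarity_network()] result.
#' @param properties property data.frame aligned with `library`.
#' @param embedding optional n x 2 coordinates.
#' @return data.frame (one row per molecule) with probability,
#'   neighbor_count, properties and optional embedding coordinates.
#' @export
screen_records <- function(library, probability, network, properties,
                           embedding = NULL) {
  stopifnot(nrow(library) == length(probability),
            nrow(library) == nrow(properties))
  rec <- data.frame(id = library$id, smiles = library$smiles,
                    probability = probability,
                    neighbor_count =
                      as.integer(network$neighbor_count[library$id]),
                    properties, stringsAsFactors = FALSE)
  if (!is.null(embedding)) {
    rec$tsne_x <- embedding[, 1]
    rec$tsne_y <- embedding[, 2]
  }
  rec
}

#' Apply the hit filters
#'
#' Evaluates every criterion for every molecule and returns the nominated
#' hits together with a complete audit table (one row per input molecule
#' regardless of outcome). A molecule is a hit iff all per-criterion flags
#' hold; molecules with missing probability fail `pass_prob` and are
#' flagged in `missing_probability`.
#'
#' @param records data.frame from [screen_records()].
#' @param criteria a [hit_criteria()].
#' @return list with `hits` (subset of `records`) and `audit` (records plus
#'   per-criterion logical columns and `hit`).
#' @export
filter_hits <- function(records, criteria = hit_criteria()) {
  stopifnot(is.data.frame(records))
  within <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  audit <- records
  audit$missing_probability <- is.na(records$probability)
  audit$pass_prob <- within(records$probability,
                            c(criteria$prob_min, criteria$prob_max))
  audit$pass_neighbors <- !is.na(records$neighbor_count) &
    records$neighbor_count >= criteria$min_neighbors
  audit$pass_hba <- within(records$hba, criteria$hba_range)
  audit$pass_hbd <- within(records$hbd, criteria$hbd_range)
  audit$pass_clogp <- within(records$logp, criteria$clogp_range)
  audit$pass_mw <- within(records$mw, criteria$mw_range)
  audit$hit <- audit$pass_prob & audit$pass_neighbors & audit$pass_hba &
    audit$pass_hbd & audit$pass_clogp & audit$pass_mw
  list(hits = records[audit$hit, , drop = FALSE], audit = audit)
}
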