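## Single-threshold Generalized Mixed Yule-Coalescent delimitation.
##
## On an ultrametric tree, branching events older than a threshold time T
## belong to a between-species (Yule-type) diversification process with rate
## lambda1 * n_d^p1; lineages inside the "clusters" (maximal subtrees whose
## crown nodes are all younger than T) follow within-species coalescent
## processes with rate lambda2 * n_k^p2 per cluster k. Branching times are
## scored by their waiting-time densities: for the inter-event interval of
## duration x_i the total branching rate is
##   b_i = lambda1 * n_d,i^p1 + lambda2 * sum_k n_k,i^p2,
## and logL = sum_i [ log(b_i) - b_i * x_i ].
## Under the null model a single process with rate lambda * n^p governs all
## events; the all-singleton threshold (below the youngest node) makes the
## mixed model collapse onto exactly that form, so the null is always nested
## in the threshold scan. The null (and any single-class fit) profiles
## lambda out in closed form; the mixed model is maximised by bounded
## L-BFGS-B over (log lambda1, p1, log lambda2, p2) from a fixed set of
## data-derived starts (deterministic, no RNG).

#' Collapse identical sequences into unique haplotypes
#'
#' Exact string equality over all columns (including gaps and ambiguity
#' characters); the representative of each haplotype is the
#' lexicographically smallest member id.
#'
#' @param a A \code{dna_alignment}.
#' @return A list with \code{alignment} (representatives only) and
#'   \code{map} (named list: representative id -> member ids).
#' @export
collapse_haplotypes <- function(a) {
  seqs <- apply(a$mat, 1L, paste, collapse = "")
  groups <- split(aln_ids(a), factor(seqs, levels = unique(seqs)))
  reps <- vapply(groups, function(m) sort(m)[1L], character(1))
  names(groups) <- reps
  groups <- groups[order(match(reps, aln_ids(a)))]
  reps <- names(groups)
  sub <- a$mat[reps, , drop = FALSE]
  structure(list(
    alignment = dna_alignment(sub, locus = a$locus, roles = a$roles[reps]),
    map = groups), class = "haplotype_map")
}

#' Build or validate an ultrametric tree for GMYC
#'
#' From an alignment, a UPGMA chronogram on K2P distances is built (the
#' desk-scale stand-in for an externally estimated clock tree); a supplied
#' \code{phylo} is validated for ultrametricity (tolerance 1e-6 of the root
#' height) and passed through.
#'
#' @param x A \code{dna_alignment} or a \code{phylo}.
#' @param deletion Deletion mode when building from an alignment.
#' @return An ultrametric \code{phylo} with attribute \code{"provenance"}
#'   (\code{"upgma"} or \code{"external"}).
#' @export
ultrametricize <- function(x, deletion = "complete") {
  if (inherits(x, "dna_alignment")) {
    tr <- upgma_tree(distance_matrix(x, deletion = deletion))
    attr(tr, "provenance") <- "upgma"
    return(tr)
  }
  if (!inherits(x, "phylo")) stop("x must be a dna_alignment or a phylo")
  depths <- ape::node.depth.edgelength(x)
  tipd <- depths[seq_len(ape::Ntip(x))]
  root_height <- max(depths)
  if (diff(range(tipd)) > 1e-6 * root_height) {
    stop("supplied tree is not ultrametric (tip depth spread ",
         signif(diff(range(tipd)), 3), " exceeds tolerance)")
  }
  attr(x, "provenance") <- "external"
  x
}

## --- internal: tree bookkeeping for the likelihood ---

## Returns, for each internal node, its height, parent and subtree tips.
.gmyc_tree_info <- function(tree) {
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("need >= 2 tips")
  if (!ape::is.binary(tree)) stop("tree must be binary (resolve polytomies first)")
  heights <- ape::branching.times(tree)  # named by node number
  nodes <- as.integer(names(heights))
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  list(ntip = ntip, nodes = nodes, heights = heights, parent = parent)
}

## Classify nodes at threshold T and assemble per-interval lineage counts.
## Returns the sufficient statistics for both classes:
##   yule:  events_n (n_d at each Yule event), exposure (x_i, n_d,i)
##   coal:  events_n (n_k at each coalescent event), exposure (x_i, n_k,i)
## plus cluster membership of tips (for entity extraction).
.gmyc_stats <- function(info, tree, T) {
  h <- info$heights
  ntip <- info$ntip
  is_yule <- h > T
  node_ids <- info$nodes
  ## cluster roots: coalescent nodes whose parent is a Yule node (or absent)
  cl_roots <- node_ids[!is_yule &
    (info$parent[node_ids] == 0L | h[as.character(info$parent[node_ids])] > T)]
  ## subtree internal nodes / tips per cluster
  cluster_of_node <- setNames(rep(0L, length(node_ids)), node_ids)
  cluster_tips <- list()
  if (length(cl_roots)) {
    desc_all <- .tip_descendants(tree)
    for (k in seq_along(cl_roots)) {
      root_k <- cl_roots[k]
      tips_k <- desc_all[[root_k]]
      cluster_tips[[k]] <- tips_k
      ## internal nodes of the cluster: coalescent nodes whose tip set is
      ## inside the cluster (all descendants of root_k)
      inside <- node_ids[vapply(node_ids, function(nd)
        nd == root_k || all(desc_all[[nd]] %in% tips_k) &&
          h[as.character(nd)] <= h[as.character(root_k)], logical(1))]
      cluster_of_node[as.character(inside)] <- k
    }
  }
  ## singleton entities: tips whose pendant edge crosses T, i.e. tips not in
  ## any cluster
  in_cluster <- if (length(cluster_tips)) unlist(cluster_tips) else integer(0)
  singles <- setdiff(seq_len(ntip), in_cluster)

  ## events in ascending height (present -> root)
  ord <- order(h)
  ev_h <- h[ord]
  ev_cluster <- cluster_of_node[ord]
  n_ev <- length(ev_h)
  x <- diff(c(0, unname(ev_h)))  # interval durations ending at each event

  ## running lineage counts during interval i (before event i fires)
  n_cl <- vapply(cluster_tips, length, integer(1))  # current count per cluster
  total <- ntip
  yule_ev_n <- numeric(0); coal_ev_n <- numeric(0)
  yule_exp_x <- numeric(n_ev); yule_exp_n <- numeric(n_ev)
  coal_exp <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    active <- n_cl >= 2L
    nd <- total - sum(n_cl[active])
    yule_exp_x[i] <- x[i]; yule_exp_n[i] <- nd
    coal_exp[[i]] <- n_cl[active]
    k <- ev_cluster[i]
    if (k == 0L) {
      yule_ev_n <- c(yule_ev_n, nd)
    } else {
      coal_ev_n <- c(coal_ev_n, n_cl[k])
      n_cl[k] <- n_cl[k] - 1L
    }
    total <- total - 1L
  }
  ## flattened coalescent exposure: (interval index, cluster lineage count)
  cidx <- integer(0); cnk <- integer(0)
  for (i in seq_len(n_ev)) {
    v <- coal_exp[[i]]
    if (length(v)) { cidx <- c(cidx, rep(i, length(v))); cnk <- c(cnk, v) }
  }
  list(
    x = unname(x), nd = yule_exp_n,
    cidx = cidx, cnk = cnk,
    yule = list(ev_n = yule_ev_n, exp_x = yule_exp_x, exp_n = yule_exp_n),
    coal = list(ev_n = coal_ev_n, exp_x = yule_exp_x, exp_n = coal_exp),
    n_clusters = length(cl_roots),
    n_entities = length(cl_roots) + length(singles),
    cluster_tips = cluster_tips,
    singleton_tips = singles)
}

## total branching rate per interval
.gmyc_rates <- function(st, lambda1, p1, lambda2, p2) {
  b <- numeric(length(st$x))
  pos <- st$nd > 0
  b[pos] <- lambda1 * st$nd[pos]^p1
  if (length(st$cidx)) {
    contrib <- lambda2 * st$cnk^p2
    agg <- rowsum(contrib, st$cidx)
    b[as.integer(rownames(agg))] <- b[as.integer(rownames(agg))] + agg[, 1L]
  }
  b
}

## waiting-time log-likelihood: sum log(b_i) - sum b_i x_i
.gmyc_loglik <- function(st, lambda1, p1, lambda2, p2) {
  b <- .gmyc_rates(st, lambda1, p1, lambda2, p2)
  if (any(b <= 0)) return(-Inf)
  sum(log(b)) - sum(b * st$x)
}

.GMYC_LAMBDA_BOUNDS <- log(c(1e-8, 1e6))
.GMYC_P_BOUNDS <- c(-2, 10)

## maximise the mixed likelihood at one threshold; deterministic multistart
.gmyc_optim <- function(st) {
  if (st$n_clusters == 0L) {
    ## no coalescent class: single-process closed-form profile
    f <- .class_fit(st$yule$ev_n, st$x, st$nd)
    return(list(logL = f$logL, lambda1 = f$lambda, p1 = f$p,
                lambda2 = NA_real_, p2 = NA_real_))
  }
  ## smart start from per-class profile fits (approximation), plus fixed
  ## alternatives covering flat, linear and coalescent-like exponents
  f1 <- .class_fit(st$yule$ev_n, st$yule$exp_x, st$yule$exp_n)
  f2 <- .class_fit(st$coal$ev_n, st$coal$exp_x, st$coal$exp_n)
  lam_for <- function(p, class) {
    ## moment-matched lambda at given p: K / A(p)
    if (class == 1L) {
      keep <- st$nd > 0
      A <- sum(st$x[keep] * st$nd[keep]^p)
      K <- length(st$yule$ev_n)
    } else {
      A <- sum(st$x[st$cidx] * st$cnk^p)
      K <- length(st$coal$ev_n)
    }
    max(min(K / max(A, 1e-300), 1e6), 1e-8)
  }
  starts <- list(
    c(f1$lambda, f1$p, f2$lambda, f2$p),
    c(lam_for(1, 1L), 1, lam_for(1, 2L), 1),
    c(lam_for(0, 1L), 0, lam_for(2, 2L), 2),
    c(lam_for(2, 1L), 2, lam_for(1, 2L), 1),
    c(lam_for(3, 1L), 3, lam_for(3, 2L), 3))
  obj <- function(par) {
    -.gmyc_loglik(st, exp(par[1L]), par[2L], exp(par[3L]), par[4L])
  }
  best <- NULL
  for (s in starts) {
    par0 <- c(log(max(min(s[1L], 1e6), 1e-8)), min(max(s[2L], -2), 10),
              log(max(min(s[3L], 1e6), 1e-8)), min(max(s[4L], -2), 10))
    fit <- tryCatch(stats::optim(par0, obj, method = "L-BFGS-B",
      lower = c(.GMYC_LAMBDA_BOUNDS[1L], .GMYC_P_BOUNDS[1L],
                .GMYC_LAMBDA_BOUNDS[1L], .GMYC_P_BOUNDS[1L]),
      upper = c(.GMYC_LAMBDA_BOUNDS[2L], .GMYC_P_BOUNDS[2L],
                .GMYC_LAMBDA_BOUNDS[2L], .GMYC_P_BOUNDS[2L])),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GMYC optimizer failed to converge from any start")
  list(logL = -best$value,
       lambda1 = exp(best$par[1L]), p1 = best$par[2L],
       lambda2 = exp(best$par[3L]), p2 = best$par[4L])
}

## Profile log-likelihood of one class: events with counts ev_n, exposures
## (x_i, n_i) (n_i may be a list of vectors for the coalescent class).
## maximises over p in [-2, 10] with lambda profiled out.
.class_fit <- function(ev_n, exp_x, exp_n, p_bounds = c(-2, 10)) {
  K <- length(ev_n)
  if (K == 0L) {
    return(list(logL = 0, lambda = NA_real_, p = NA_real_))
  }
  is_list <- is.list(exp_n)
  S <- sum(log(ev_n))
  A <- function(p) {
    if (is_list) {
      sum(vapply(seq_along(exp_x), function(i) {
        v <- exp_n[[i]]
        v <- v[v > 0]  # no lineages -> no rate, for any exponent
        if (length(v)) exp_x[i] * sum(v^p) else 0
      }, numeric(1)))
    } else {
      keep <- exp_n > 0
      sum(exp_x[keep] * exp_n[keep]^p)
    }
  }
  obj <- function(p) {
    a <- A(p)
    if (a <= 0) return(-Inf)
    K * log(K / a) + p * S - K
  }
  grid <- seq(p_bounds[1L], p_bounds[2L], by = 0.5)
  vals <- vapply(grid, obj, numeric(1))
  j <- which.max(vals)
  lo <- grid[max(1L, j - 1L)]; hi <- grid[min(length(grid), j + 1L)]
  opt <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  p_hat <- if (opt$objective >= vals[j]) opt$maximum else grid[j]
  logL <- max(opt$objective, vals[j])
  list(logL = logL, lambda = K / A(p_hat), p = p_hat)
}

#' GMYC mixed-model log-likelihood at a fixed threshold
#'
#' @param tree An ultrametric binary \code{phylo}.
#' @param T Threshold time (strictly between 0 and the root height).
#' @param params List with \code{lambda1}, \code{p1}, \code{lambda2},
#'   \code{p2}. When NULL, the likelihood is profiled (maximised over all
#'   four parameters).
#' @return The log-likelihood (scalar). With \code{params = NULL} the
#'   attributes \code{"lambda1"}, \code{"p1"}, \code{"lambda2"}, \code{"p2"}
#'   carry the maximisers.
#' @export
gmyc_likelihood <- function(tree, T, params = NULL) {
  tree <- ultrametricize(tree)
  info <- .gmyc_tree_info(tree)
  root_h <- max(info$heights)
  if (!(T > 0 && T < root_h)) stop("T must lie strictly in (0, root height)")
  st <- .gmyc_stats(info, tree, T)
  if (is.null(params)) {
    f <- .gmyc_optim(st)
    out <- f$logL
    attributes(out) <- list(lambda1 = f$lambda1, p1 = f$p1,
                            lambda2 = f$lambda2, p2 = f$p2)
    return(out)
  }
  .gmyc_loglik(st, params$lambda1, params$p1,
               if (is.null(params$lambda2)) 0 else params$lambda2,
               if (is.null(params$p2)) 1 else params$p2)
}

#' Fit the single-threshold GMYC model
#'
#' Scans candidate thresholds (midpoints between consecutive distinct node
#' heights, plus one below the youngest node so the all-singleton model --
#' which coincides with the null single-process model -- is always in the
#' candidate set), profiles the four rate parameters at each, and compares
#' the best fit against the null by a likelihood-ratio test (chi-square,
#' 3 df by default).
#'
#' @param tree An ultrametric binary \code{phylo} (>= 3 tips).
#' @param conf_delta Log-likelihood drop defining the threshold confidence
#'   set (default 1.92, the chi-square_1 95 percent half-width).
#' @param p_value_method \code{"scan"} (default): Bonferroni adjustment of
#'   the per-threshold chi-square 2 df test across the scanned candidate
#'   thresholds -- the threshold is a nuisance parameter absent under the
#'   null, so the unadjusted test over-rejects; \code{"chisq3"}: the classic
#'   single-threshold convention (2 extra rate parameters + the threshold);
#'   \code{"boundary"}: equal mixture of chi-square 2 and 3 df.
#' @return An object of class \code{gmyc_fit}.
#' @export
gmyc_fit <- function(tree, conf_delta = 1.92,
                     p_value_method = c("scan", "chisq3", "boundary")) {
  p_value_method <- match.arg(p_value_method)
  tree <- ultrametricize(tree)
  if (ape::Ntip(tree) < 3L) stop("need >= 3 tips")
  info <- .gmyc_tree_info(tree)
  hs <- sort(unique(unname(info$heights)))
  ## merge numerically tied heights so no candidate threshold can fall
  ## between two events that are equal up to floating error (such a cut
  ## creates a near-zero interval with an arbitrarily high fitted rate)
  tol <- 1e-7 * max(hs)
  keep <- c(TRUE, diff(hs) > tol)
  hs <- hs[keep]
  if (length(hs) == 1L) {
    stop("degenerate tree: all internal nodes at the same height")
  }
  cands <- c(hs[1L] / 2, (hs[-length(hs)] + hs[-1L]) / 2)
  fits <- lapply(cands, function(Tc) {
    st <- .gmyc_stats(info, tree, Tc)
    f <- .gmyc_optim(st)
    list(T = Tc, logL = f$logL, f = f, st = st)
  })
  logLs <- vapply(fits, `[[`, numeric(1), "logL")
  ## null single-process fit: during the interval ending at the i-th event
  ## (ascending heights) there are ntip - i + 1 lineages
  hs_all <- sort(unname(info$heights))
  nvec <- info$ntip - seq_along(hs_all) + 1L
  null <- .class_fit(nvec, diff(c(0, hs_all)), nvec)
  best <- which.max(logLs)
  fit <- fits[[best]]
  LR <- max(0, 2 * (fit$logL - null$logL))
  n_scanned <- length(cands) - 1L  # interior candidates (boundary = null)
  p_value <- switch(p_value_method,
    scan = min(1, max(1L, n_scanned) *
                 stats::pchisq(LR, df = 2, lower.tail = FALSE)),
    chisq3 = stats::pchisq(LR, df = 3, lower.tail = FALSE),
    boundary = 0.5 * stats::pchisq(LR, df = 2, lower.tail = FALSE) +
               0.5 * stats::pchisq(LR, df = 3, lower.tail = FALSE))
  conf_idx <- which(logLs >= fit$logL - conf_delta)
  ent_counts <- vapply(fits, function(f) f$st$n_entities, integer(1))
  tips <- tree$tip.label
  members <- c(lapply(fit$st$cluster_tips, function(i) tips[i]),
               as.list(tips[fit$st$singleton_tips]))
  grp <- integer(length(tips)); names(grp) <- tips
  for (k in seq_along(members)) grp[members[[k]]] <- k
  grp <- match(grp, unique(grp)); names(grp) <- tips
  entities <- structure(grp, n_groups = length(members),
                        class = "species_partition")
  structure(list(
    threshold_time = fit$T,
    lambda1 = fit$f$lambda1, p1 = fit$f$p1,
    lambda2 = fit$f$lambda2, p2 = fit$f$p2,
    logL_gmyc = fit$logL, logL_null = null$logL,
    LR = LR, p_value = p_value,
    n_clusters = fit$st$n_clusters, n_entities = fit$st$n_entities,
    entities = entities,
    confidence_thresholds = cands[conf_idx],
    confidence_entity_range = range(ent_counts[conf_idx]),
    support = data.frame(threshold = cands, logL = logLs,
                         n_entities = ent_counts)),
    class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf("GMYC single-threshold fit\n  threshold T = %.5g\n", x$threshold_time))
  cat(sprintf("  logL(GMYC) = %.3f, logL(null) = %.3f, LR = %.3f, p = %.3g\n",
              x$logL_gmyc, x$logL_null, x$LR, x$p_value))
  cat(sprintf("  %d cluster(s), %d entit%s; 95%% CI of entities: %d-%d\n",
              x$n_clusters, x$n_entities,
              if (x$n_entities == 1L) "y" else "ies",
              x$confidence_entity_range[1L], x$confidence_entity_range[2L]))
  invisible(x)
}

#' Write a GMYC fit report (entities TSV + JSON summary)
#'
#' @param fit A \code{gmyc_fit}.
#' @param entities_path,report_path Output paths (either may be NULL).
#' @export
write_gmyc_report <- function(fit, entities_path = NULL, report_path = NULL) {
  if (!is.null(entities_path)) write_partition(fit$entities, entities_path)
  if (!is.null(report_path)) {
    jsonlite::write_json(list(
      threshold_time = fit$threshold_time,
      lambda1 = fit$lambda1, p1 = fit$p1,
      lambda2 = fit$lambda2, p2 = fit$p2,
      logL_gmyc = fit$logL_gmyc, logL_null = fit$logL_null,
      LR = fit$LR, p_value = fit$p_value,
      n_clusters = fit$n_clusters, n_entities = fit$n_entities,
      confidence_entity_range = fit$confidence_entity_range),
      report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}
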