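# Two-level grouping: greedy sequence-identity clusters, then
# topology/window sub-clusters of mutually comparable members.

# identity between two sequences: identical matched columns / shorter length
seq_identity <- function(s1, s2, params = alignment_params()) {
  if (s1 == s2) return(1)
  if (nchar(s1) <= nchar(s2)) { q <- s1; r <- s2 } else { q <- s2; r <- s1 }
  a <- align_glocal(q, r, params)
  p <- a$aligned_pairs
  if (nrow(p) == 0) return(0)
  qs <- strsplit(q, "")[[1]][p[, 1]]
  rs <- strsplit(r, "")[[1]][p[, 2]]
  sum(qs == rs) / min(nchar(s1), nchar(s2))
}

#' Greedy incremental sequence-identity clustering
#'
#' Instances are sorted by sequence length (descending, ties by instance id)
#' and each joins the first existing cluster whose representative it matches
#' at or above `threshold` identity (identical matched columns divided by
#' the shorter sequence length), otherwise it founds a new cluster — the
#' greedy longest-first scheme of common sequence clustering tools. The
#' fixed sort makes the result invariant to input order.
#'
#' @param instances list of `domain_instance` objects (sequences used).
#' @param threshold identity fraction, default 0.95.
#' @param params alignment parameters for the identity computation.
#' @return list of `seq_cluster` objects: `cluster_id`, `representative`
#'   (instance id), `members` (instance ids).
#' @export
greedy_identity_cluster <- function(instances, threshold = 0.95,
                                    params = alignment_params()) {
  if (!length(instances)) return(list())
  ids <- vapply(instances, function(x) x$instance_id, "")
  seqs <- vapply(instances, function(x) x$seq, "")
  ord <- order(-nchar(seqs), ids)
  reps <- character(0); members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (seq_identity(seqs[i], reps[k], params) >= threshold) {
        members[[k]] <- c(members[[k]], ids[i]); placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, seqs[i]); members[[length(reps)]] <- ids[i] }
  }
  lapply(seq_along(reps), function(k)
    structure(list(cluster_id = sprintf("C%03d", k),
                   representative = members[[k]][1], members = members[[k]]),
              class = "seq_cluster"))
}

#' Split a sequence cluster into topology/window sub-clusters
#'
#' Members are partitioned by topology code; within a topology, members are
#' linked (single linkage) when their resolved reference windows overlap by
#' at least `window_agreement` of the shorter window. This reproduces the
#' two splitting rules of the census: a region annotated to several
#' topologies yields one sub-cluster per topology, and disjoint resolved
#' windows of one topology yield separate sub-clusters.
#'
#' @param cluster a `seq_cluster`.
#' @param info data frame with columns `instance_id`, `topology_code`,
#'   `win_start`, `win_end` covering the cluster members.
#' @param window_agreement required mutual-overlap fraction, default 0.9.
#' @return list of `sub_cluster` objects: `subcluster_id`, `topology_code`,
#'   `window` (median member window), `members`.
#' @export
subcluster <- function(cluster, info, window_agreement = 0.9) {
  rows <- info[match(cluster$members, info$instance_id), , drop = FALSE]
  if (anyNA(rows$instance_id)) stop_fc("member(s) missing from info table",
                                       "fc_validation_error")
  out <- list()
  for (topo in sort(unique(rows$topology_code))) {
    sub <- rows[rows$topology_code == topo, , drop = FALSE]
    comp <- window_components(sub$win_start, sub$win_end, window_agreement)
    for (g in sort(unique(comp))) {
      m <- sub[comp == g, , drop = FALSE]
      out[[length(out) + 1]] <- list(topology_code = topo,
                                     start = min(m$win_start),
                                     window = c(round(median(m$win_start)),
                                                round(median(m$win_end))),
                                     members = m$instance_id)
    }
  }
  ord <- order(vapply(out, function(x) x$topology_code, ""),
               vapply(out, function(x) x$start, 1))
  lapply(seq_along(ord), function(k) {
    x <- out[[ord[k]]]
    structure(list(subcluster_id = sprintf("%s_S%02d", cluster$cluster_id, k),
                   topology_code = x$topology_code, window = x$window,
                   members = x$members), class = "sub_cluster")
  })
}

# single-linkage connected components under the window-overlap rule
window_components <- function(start, end, agreement) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ov <- min(end[i], end[j]) - max(start[i], start[j]) + 1
      shorter <- min(end[i] - start[i], end[j] - start[j]) + 1
      if (ov >= agreement * shorter) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Full two-level grouping of domain instances
#'
#' Convenience wrapper: greedy identity clustering followed by
#' topology/window sub-clustering of every cluster.
#'
#' @param instances list of `domain_instance` objects whose `window` and
#'   `topology_code` fields are populated.
#' @param threshold sequence-identity threshold, default 0.95.
#' @param window_agreement window-overlap fraction, default 0.9.
#' @return data frame `instance_id`, `cluster_id`, `subcluster_id`,
#'   `topology_code`, `win_start`, `win_end`.
#' @export
group_instances <- function(instances, threshold = 0.95,
                            window_agreement = 0.9) {
  info <- do.call(rbind, lapply(instances, function(x) {
    w <- x$window %||% range(residue_table(x)$resno)
    data.frame(instance_id = x$instance_id, topology_code = x$topology_code,
               win_start = w[1], win_end = w[2], stringsAsFactors = FALSE)
  }))
  clusters <- greedy_identity_cluster(instances, threshold)
  rows <- list()
  for (cl in clusters) {
    for (sc in subcluster(cl, info, window_agreement)) {
      rows[[length(rows) + 1]] <- data.frame(
        instance_id = sc$members, cluster_id = cl$cluster_id,
        subcluster_id = sc$subcluster_id, topology_code = sc$topology_code,
        win_start = sc$window[1], win_end = sc$window[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$instance_id), , drop = FALSE]
}
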