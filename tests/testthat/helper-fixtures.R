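# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_head <- function() fx("head", head_model())
fx_mon32 <- function() fx("mon32", build_montage(32))
fx_mon110 <- function() fx("mon110", build_montage(110))
fx_grid_small <- function() fx("grid_small",
                               build_source_grid(fx_head(), 250))
fx_lf_small <- function() fx("lf_small",
                             compute_lead_field(fx_grid_small(), fx_mon32(),
                                                fx_head()))

# subject-level ERP list from an array subjects x channels x samples
erps_from_array <- function(arr, rate = 500, window = c(-100, 298)) {
  lapply(seq_len(dim(arr)[1]), function(s)
    erp(arr[s, , ], rate, window, n_trials = 1, level = "subject"))
}

# connected subset of a given size inside one montage cluster (BFS order)
connected_subset <- function(montage, cluster, size) {
  members <- which(montage$clusters == cluster)
  adj <- lapply(montage$adjacency, function(nb)
    nb[montage$clusters[nb] == cluster])
  start <- members[1]
  out <- integer(0)
  queue <- start
  seen <- logical(length(montage$labels))
  seen[start] <- TRUE
  while (length(queue) && length(out) < size) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (length(out) < size)
    stop("cluster ", cluster, " cannot host a connected subset of ", size)
  out
}
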