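#' Place neurons of one hemisphere in and on a cube of cerebellar tissue
#'
#' Granular-layer cells (mf glomeruli, gr, Go) are placed uniformly at random
#' inside a cube of edge `cube_edge` um; molecular/Purkinje-layer cells (ba,
#' Pk) are placed in a slab of depth `molecular_depth` sitting on the cube's
#' top face. No two cells may be closer than the sum of their exclusion
#' radii; placement is by rejection sampling, largest radii first, with a
#' bounded number of attempts per cell.
#'
#' @param specs population table as returned by [population_specs()].
#' @param cube_edge cube edge length in um (default 100).
#' @param rng_seed integer seed for reproducible placement; `NULL` uses the
#'   current RNG stream.
#' @param molecular_depth depth (um) of the molecular slab above the cube.
#' @param max_attempts rejection-sampling attempts allowed per cell before a
#'   packing-infeasible error is raised.
#' @return data.frame with columns `neuron_id` (1..N, contiguous per
#'   population in the order of `specs`), `population`, `x`, `y`, `z`.
#' @export
allocate_positions <- function(specs, cube_edge = 100, rng_seed = NULL,
                               molecular_depth = 20, max_attempts = 5000L) {
  stopifnot(cube_edge > 0, all(specs$count > 0))
  with_seed(rng_seed, {
    # place largest radii first so small cells fill remaining gaps
    place_order <- order(match(specs$layer, c("granular", "molecular")),
                         -specs$exclusion_radius)
    n_total <- sum(specs$count)
    pos <- matrix(NA_real_, n_total, 3)
    rad <- numeric(n_total)
    pop <- character(n_total)
    k <- 0L
    for (i in place_order) {
      r <- specs$exclusion_radius[i]
      zlim <- if (specs$layer[i] == "granular") c(0, cube_edge)
              else c(cube_edge, cube_edge + molecular_depth)
      for (j in seq_len(specs$count[i])) {
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
          cand <- c(stats::runif(1, 0, cube_edge), stats::runif(1, 0, cube_edge),
                    stats::runif(1, zlim[1], zlim[2]))
          ok <- if (k == 0L) TRUE else {
            d2 <- (pos[1:k, 1] - cand[1])^2 + (pos[1:k, 2] - cand[2])^2 +
                  (pos[1:k, 3] - cand[3])^2
            all(d2 >= (rad[1:k] + r)^2)
          }
          if (ok) {
            k <- k + 1L
            pos[k, ] <- cand
            rad[k] <- r
            pop[k] <- specs$label[i]
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop(sprintf(
            "packing infeasible: could not place %s cell %d/%d after %d attempts; ",
            specs$label[i], j, specs$count[i], max_attempts),
            "exclusion radii or counts are incompatible with the cube volume")
      }
    }
    # assign ids contiguously in the canonical population order of `specs`
    ord <- order(match(pop, specs$label))
    data.frame(neuron_id = seq_len(n_total),
               population = pop[ord],
               x = pos[ord, 1], y = pos[ord, 2], z = pos[ord, 3],
               stringsAsFactors = FALSE)
  })
}

#' Wire a hemisphere by the nearest-neighbour rule
#'
#' For every connection class and every target cell, connects the
#' convergence-many nearest distinct source cells (Euclidean distance in the
#' placement volume, ties broken by lower source `neuron_id`). Divergence
#' ratios are not enforced; convergence is the binding constraint.
#'
#' @param positions data.frame from [allocate_positions()].
#' @param ratios connection table as returned by [connection_ratios()].
#' @return a synapse table: data.frame with columns `pre`, `post`, `class`,
#'   `nature` and `weight` (all `NA` until [draw_initial_weights()]).
#' @export
wire_nearest_neighbor <- function(positions, ratios = connection_ratios()) {
  coords <- as.matrix(positions[, c("x", "y", "z")])
  out <- vector("list", nrow(ratios))
  for (i in seq_len(nrow(ratios))) {
    src_sel <- positions$population == ratios$src[i]
    dst_sel <- positions$population == ratios$dst[i]
    if (!any(src_sel) || !any(dst_sel))
      stop("positions do not cover populations of class ", ratios$class[i])
    conv <- ratios$convergence[i]
    src_id <- positions$neuron_id[src_sel]
    dst_id <- positions$neuron_id[dst_sel]
    if (conv > length(src_id))
      stop(sprintf("class %s: convergence %d exceeds source population size %d",
                   ratios$class[i], conv, length(src_id)))
    S <- coords[src_sel, , drop = FALSE]
    D <- coords[dst_sel, , drop = FALSE]
    pre <- matrix(0L, length(dst_id), conv)
    for (j in seq_along(dst_id)) {
      d2 <- (S[, 1] - D[j, 1])^2 + (S[, 2] - D[j, 2])^2 + (S[, 3] - D[j, 3])^2
      pre[j, ] <- src_id[order(d2, src_id)[seq_len(conv)]]
    }
    out[[i]] <- data.frame(pre = as.integer(t(pre)),
                           post = rep(dst_id, each = conv),
                           class = ratios$class[i],
                           nature = ratios$nature[i],
                           weight = NA_real_,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# truncated-normal N(mu, sd) on [lo, hi] by rejection (vectorized)
rtruncnorm_rej <- function(n, mu = 0.9, sd = 0.1, lo = 0.8, hi = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(n - length(out), 64L) * 2L, mu, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Draw and normalize initial synaptic weights
#'
#' Each synapse receives a magnitude drawn from a normal distribution
#' (mu = 0.9, sd = 0.1) truncated to \[0.8, 1\], multiplied by the
#' normalizing constant d = 1 / (number of inputs of the same connection
#' class converging on the postsynaptic cell). Inhibitory-class weights are
#' stored with negative sign.
#'
#' @param table synapse table from [wire_nearest_neighbor()].
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @return the synapse table with its `weight` column filled.
#' @export
draw_initial_weights <- function(table, rng_seed = NULL) {
  with_seed(rng_seed, {
    key <- paste(table$post, table$class)
    indeg <- ave(rep(1, nrow(table)), key, FUN = sum)
    w <- rtruncnorm_rej(nrow(table)) / indeg
    table$weight <- ifelse(table$nature == "inhibitory", -w, w)
    table
  })
}

#' Encode a synapse table in Address Event Representation
#'
#' AER describes a sparse network with four vectors: `ID` (the neuron ids),
#' `N_P` (number of presynaptic partners per neuron), and the stacked `P`
#' (presynaptic ids) and `W` (signed weights), ordered by postsynaptic
#' neuron. A neuron's presynaptic slice is recovered by prefix-summing
#' `N_P`; the `ptr` offsets cache that prefix sum.
#'
#' @param table synapse table (rows may be in any order; within one
#'   postsynaptic cell the original row order is preserved).
#' @param positions data.frame from [allocate_positions()] defining the
#'   neuron ids and populations.
#' @return an object of class `aer_network`: list with `ID`, `N_P`, `P`,
#'   `W`, `ptr`, `population_ranges` and `n_syn`.
#' @export
encode_aer <- function(table, positions) {
  ids <- positions$neuron_id
  if (any(!(table$pre %in% ids)) || any(!(table$post %in% ids)))
    stop("synapse table references unknown neuron ids")
  n <- length(ids)
  stopifnot(!anyDuplicated(ids), all(sort(ids) == seq_len(n)))
  ord <- order(table$post, seq_len(nrow(table)))
  post_sorted <- table$post[ord]
  N_P <- tabulate(post_sorted, nbins = n)
  ranges <- lapply(split(ids, positions$population), range)
  # populations must occupy contiguous id blocks
  for (lab in names(ranges)) {
    sel <- positions$population == lab
    stopifnot(sum(sel) == diff(ranges[[lab]]) + 1L)
  }
  structure(list(ID = as.integer(seq_len(n)),
                 N_P = as.integer(N_P),
                 P = as.integer(table$pre[ord]),
                 W = as.numeric(table$weight[ord]),
                 ptr = c(0L, cumsum(as.integer(N_P))),
                 population_ranges = ranges[unique(positions$population)],
                 n_syn = nrow(table)),
            class = "aer_network")
}

#' Decode an AER network back into a synapse table
#'
#' Inverse of [encode_aer()]: reconstructs the (pre, post, class, nature,
#' weight) rows, with connection class and nature inferred from the
#' population id ranges (every source/target population pair maps to exactly
#' one class).
#'
#' @param net an `aer_network`.
#' @param ratios connection table used to label classes.
#' @return synapse table data.frame ordered by postsynaptic neuron.
#' @export
decode_aer <- function(net, ratios = connection_ratios()) {
  post <- rep(net$ID, net$N_P)
  pop_of <- function(id) {
    out <- character(length(id))
    for (lab in names(net$population_ranges)) {
      r <- net$population_ranges[[lab]]
      out[id >= r[1] & id <= r[2]] <- lab
    }
    out
  }
  key <- paste(pop_of(net$P), pop_of(post), sep = "_")
  m <- match(key, paste(ratios$src, ratios$dst, sep = "_"))
  data.frame(pre = net$P, post = post,
             class = ratios$class[m], nature = ratios$nature[m],
             weight = net$W, stringsAsFactors = FALSE)
}

#' Validate realized connectivity against the requested ratios
#'
#' Report-only check: realized per-class convergence statistics over all
#' postsynaptic cells, total synapse count, and flags for any class whose
#' realized convergence deviates from the request.
#'
#' @param net an `aer_network`.
#' @param ratios connection table the network was built from.
#' @return list with `per_class` (data.frame), `total_synapses` and
#'   `deviations` (character vector, empty when clean).
#' @export
validate_network <- function(net, ratios = connection_ratios()) {
  tab <- decode_aer(net, ratios)
  per <- lapply(seq_len(nrow(ratios)), function(i) {
    r <- net$population_ranges[[ratios$dst[i]]]
    n_dst <- r[2] - r[1] + 1L
    sel <- tab$class == ratios$class[i]
    indeg <- tabulate(tab$post[sel] - r[1] + 1L, nbins = n_dst)
    outdeg_mean <- sum(sel) / (diff(net$population_ranges[[ratios$src[i]]]) + 1L)
    data.frame(class = ratios$class[i], requested = ratios$convergence[i],
               conv_min = min(indeg), conv_mean = mean(indeg),
               conv_max = max(indeg), div_mean = outdeg_mean,
               n_synapses = sum(sel), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  dev <- per$class[per$conv_min != per$requested | per$conv_max != per$requested]
  list(per_class = per, total_synapses = nrow(tab),
       deviations = as.character(dev))
}

#' Build one complete hemisphere
#'
#' Convenience pipeline: place neurons, wire nearest-neighbour, draw
#' normalized initial weights, and AER-encode. A single seed drives the
#' whole build, so identical seeds give bit-identical hemispheres and
#' different seeds give unique wiring.
#'
#' @param rng_seed integer build seed.
#' @param specs,ratios,cube_edge,molecular_depth see [allocate_positions()]
#'   and [wire_nearest_neighbor()].
#' @param side `"left"` or `"right"` (metadata only; hemispheres are
#'   anatomically equivalent).
#' @return `aer_network` with `positions`, `side` and `build_seed` attached.
#' @export
build_hemisphere <- function(rng_seed, specs = population_specs(),
                             ratios = connection_ratios(), cube_edge = 100,
                             molecular_depth = 20, side = "left") {
  with_seed(rng_seed, {
    pos <- allocate_positions(specs, cube_edge, rng_seed = NULL,
                              molecular_depth = molecular_depth)
    tab <- wire_nearest_neighbor(pos, ratios)
    tab <- draw_initial_weights(tab, rng_seed = NULL)
    net <- encode_aer(tab, pos)
    net$positions <- pos
    net$side <- side
    net$build_seed <- rng_seed
    net
  })
}

#' Export / import a network as plain text
#'
#' Writes the synapse table as a CSV edge list plus a JSON sidecar holding
#' the population id ranges and the build seed; `read_network()` restores an
#' equivalent `aer_network` (positions are stored in the sidecar as well).
#'
#' @param net an `aer_network` (ideally from [build_hemisphere()]).
#' @param path base path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return `write_network()` the base path, invisibly; `read_network()` the
#'   restored `aer_network`.
#' @export
write_network <- function(net, path) {
  tab <- decode_aer(net)
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(population_ranges = net$population_ranges,
               build_seed = net$build_seed, side = net$side,
               positions = net$positions)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  tab <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pos <- as.data.frame(meta$positions)
  net <- encode_aer(tab, pos)
  net$positions <- pos
  net$side <- meta$side
  net$build_seed <- meta$build_seed
  net
}

#' @export
print.aer_network <- function(x, ...) {
  n_pop <- vapply(x$population_ranges, function(r) r[2] - r[1] + 1L, integer(1))
  cat("AER network:", length(x$ID), "neurons,", x$n_syn, "synapses\n")
  cat(paste(sprintf("%s=%d", names(n_pop), n_pop), collapse = ", "), "\n")
  invisible(x)
}
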