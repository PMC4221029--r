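#' Population specifications for one cerebellar hemisphere
#'
#' Returns the default per-hemisphere population table: mossy-fiber glomeruli
#' (mf), granule cells (gr), Golgi cells (Go), basket/stellate cells (ba) and
#' Purkinje cells (Pk). Counts follow reported volumetric densities for a
#' 100 um cube of cerebellar cortex (4096 gr, 274 ba) and anatomical
#' cell-count ratios (28 Go, 15 Pk), plus 281 mf glomeruli, for a total of
#' 4694 nodes per hemisphere.
#'
#' @param counts optional named integer vector overriding the default counts
#'   (names among `mf`, `gr`, `Go`, `ba`, `Pk`).
#' @return a data.frame with columns `label`, `count`, `layer`
#'   (`"granular"` cells live inside the cube, `"molecular"` cells sit on
#'   top of it) and `exclusion_radius` (um, for non-overlap placement).
#' @examples
#' specs <- population_specs()
#' sum(specs$count) # 4694
#' @export
population_specs <- function(counts = NULL) {
  specs <- data.frame(
    label = c("mf", "gr", "Go", "ba", "Pk"),
    count = c(281L, 4096L, 28L, 274L, 15L),
    layer = c("granular", "granular", "granular", "molecular", "molecular"),
    # ba/Pk radii are smaller than their granular counterparts would suggest:
    # 274 ba must pack pairwise-disjointly into the 100x100x20 um molecular slab
    exclusion_radius = c(4, 2, 8, 3, 8),
    stringsAsFactors = FALSE
  )
  if (!is.null(counts)) {
    stopifnot(all(names(counts) %in% specs$label))
    specs$count[match(names(counts), specs$label)] <- as.integer(counts)
  }
  if (any(specs$count <= 0L)) stop("population counts must be positive")
  specs
}

#' Connection-class table: convergence/divergence ratios
#'
#' The nine connection classes of the microcircuit with their per-target-cell
#' convergence (number of presynaptic partners) and nominal divergence, and
#' the nature of each class (excitatory or inhibitory). Convergence is the
#' binding constraint for the nearest-neighbour wiring; divergence is the
#' soft ratio implied by the population counts.
#'
#' @return data.frame with columns `class`, `src`, `dst`, `convergence`,
#'   `divergence`, `nature`.
#' @export
connection_ratios <- function() {
  data.frame(
    class = c("mf_gr", "Go_gr", "mf_Go", "gr_Go", "ba_Go",
              "gr_ba", "Pk_ba", "gr_Pk", "ba_Pk"),
    src   = c("mf", "Go", "mf", "gr", "ba", "gr", "Pk", "gr", "ba"),
    dst   = c("gr", "gr", "Go", "Go", "Go", "ba", "ba", "Pk", "Pk"),
    convergence = c(4L, 4L, 66L, 1639L, 28L, 41L, 3L, 1024L, 110L),
    divergence  = c(59L, 586L, 7L, 12L, 3L, 3L, 55L, 4L, 7L),
    nature = c("excitatory", "inhibitory", "excitatory", "excitatory",
               "inhibitory", "excitatory", "inhibitory", "excitatory",
               "inhibitory"),
    stringsAsFactors = FALSE
  )
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
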