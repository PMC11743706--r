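# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers never observe a side effect on the random
#' stream.  A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic fan-out of one global seed into independent per-stage seeds.
# Offsets are fixed per stage so every stage is reproducible on its own.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 1L, series = 2L, oscillation = 3L, split = 4L,
               optimize = 5L, misc = 6L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + 100003L * offsets[[stage]]) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (strict && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict && x < lower) stopf("'%s' must be >= %g", name, lower)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stopf("'%s' must be an integer", name)
  invisible(as.integer(x))
}

#' Anatomical labels of the ten plantar regions
#'
#' Region order follows the standard pressure-plate zoning used throughout
#' the package: region 1 is the hallux, region 2 the second to fifth toes,
#' regions 3-7 the first to fifth metatarsals, region 8 the midfoot,
#' region 9 the medial heel and region 10 the lateral heel.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' plantar_regions()
plantar_regions <- function() {
  c("hallux", "toes_2_5",
    "metatarsal_1", "metatarsal_2", "metatarsal_3", "metatarsal_4",
    "metatarsal_5", "midfoot", "medial_heel", "lateral_heel")
}

N_REGIONS <- 10L
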