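#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import Matrix
#' @importFrom stats var rnorm runif rbinom pchisq setNames model.matrix
#' @importFrom methods as
NULL

SEMEN_TRAITS <- c("VE", "SC", "MS", "NSP", "NMSP")

# Legal trait ranges used by the error-data filter. MS is a proportion of
# forward-moving sperm; NSP = VE * SC and NMSP = NSP * MS, so their upper
# bound is the product of the factor bounds.
trait_range <- function(trait) {
  switch(trait,
    VE   = c(0, 30),
    SC   = c(0, 40),
    MS   = c(0, 1),
    NSP  = c(0, 30 * 40),
    NMSP = c(0, 30 * 40),
    abort(paste0(
      "Unknown trait '", trait, "'. Valid traits: ",
      paste(SEMEN_TRAITS, collapse = ", ")
    ))
  )
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
}
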