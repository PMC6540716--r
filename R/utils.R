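#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not disturb a user's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Monoisotopic masses of the elements occurring in the shipped rule table.
.monoisotopic <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

#' Monoisotopic mass of a molecular formula
#'
#' Computes the monoisotopic (exact) mass of a formula string such as
#' `"C6H10O5"` from tabulated atomic masses. Only C, H, N, O, P and S are
#' supported; these cover the diagnostic fragments and neutral losses used
#' by the compound-class rules.
#'
#' @param formula character vector of molecular formulas.
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C6H10O5")  # hexose neutral loss
#' monoisotopic_mass(c("SO3", "HPO3"))
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", f)) {
      stop("cannot parse formula: ", f, call. = FALSE)
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    total <- 0
    for (p in parts) {
      el <- gsub("[0-9]", "", p)
      n <- gsub("[A-Za-z]", "", p)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.monoisotopic)) {
        stop("element not tabulated: ", el, call. = FALSE)
      }
      total <- total + .monoisotopic[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
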