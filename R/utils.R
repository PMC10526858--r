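#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor kruskal.test ks.test mad median p.adjust pnorm
#'   quantile rnbinom rnorm rpois runif sd setNames var wilcox.test approx
#' @importFrom utils read.csv write.csv
NULL

# Deterministic 31-bit child seed for a named substream of a root seed.
# One root seed per run; each stochastic component draws from its own
# substream so tests can pin individual stages.
child_seed <- function(seed, what) {
  stopifnot(is.character(what), length(what) == 1L)
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_contract("'%s' must be a single finite number", name)
  if (strict_min && x <= min)
    stop_contract("'%s' must be > %g (got %g)", name, min, x)
  if (!strict_min && x < min)
    stop_contract("'%s' must be >= %g (got %g)", name, min, x)
  if (x > max)
    stop_contract("'%s' must be <= %g (got %g)", name, max, x)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_contract("'%s' must be a whole number (got %g)", name, x)
  invisible(x)
}
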