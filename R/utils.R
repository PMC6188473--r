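#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed for a named stage
#'
#' Fans a single user-supplied seed out into independent, deterministic
#' sub-seeds, one per named stage (or per iteration), so that results do not
#' depend on the order in which stages consume random numbers.
#'
#' @param seed Integer base seed.
#' @param stage Character label of the stage or substream.
#' @return A single integer suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 1000003
  # stays exact in double arithmetic for |seed| < 2^31
  as.integer(((abs(seed) %% 2147483647) * 1000003 + h * 8191 + 1) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version_string <- function() {
  as.character(utils::packageVersion("orthocell"))
}
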