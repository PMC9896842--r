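# fill the fixed antithetic draw set used by the amplitude bias correction
# without disturbing the user's RNG stream
.onLoad <- function(libname, pkgname) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(987654321L)
  z <- matrix(stats::rnorm(64 * 4), 64, 4)
  if (is.null(old)) {
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  z <- rbind(z, -z)                      # exact zero mean
  s <- crossprod(z) / nrow(z)
  z <- z %*% solve(chol(s))              # exact identity covariance
  assign("bc_z", z, envir = .ppg_env)
}
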