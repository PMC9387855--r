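#' Expand a master seed into a stage-specific subseed
#'
#' Deterministic counter-based expansion: every stochastic stage of the
#' pipeline derives its own seed from the master seed plus a short tag, so a
#' single integer reproduces the whole analysis while stages stay
#' independently re-runnable. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param tag Character tag naming the stage (e.g. `"rest"`, `"decode"`).
#' @param counter Optional extra integer (e.g. subject or permutation index).
#' @return An integer seed.
#' @export
expand_seed <- function(master, tag = "", counter = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 131 + as.numeric(counter) + 1) %% m
  as.integer(h %% (m - 1) + 1)
}
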