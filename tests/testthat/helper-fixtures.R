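# Shared fixtures, built in code. A small panel simulated once per test
# run and reused by tests that only need "some realistic data".

smallPanel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(nLines = 40, nVariants = 600, seed = 404)
      geno <- simulateGenotypes(cfg)
      cache <<- c(list(geno = geno, config = cfg),
                  simulatePhenotypes(geno, cfg))
    }
    cache
  }
})

# balanced record frame for n lines over the standard 2 x 3 grid
recordGrid <- function(lines) {
  grid <- expand.grid(sex = c("F", "M"), temperature = c(18, 25, 28),
                      stringsAsFactors = FALSE)
  data.frame(line = rep(lines, each = nrow(grid)),
             sex = rep(grid$sex, length(lines)),
             temperature = rep(grid$temperature, length(lines)),
             stringsAsFactors = FALSE)
}

# independent dense REML surface for one kernel + residual, written from
# the textbook formula with solve()/determinant() only (oracle; shares no
# code with the package internals)
oracleRemlLoglik <- function(y, K, s2k, s2e) {
  q <- length(y)
  V <- s2k * K + diag(s2e, q)
  Vi <- solve(V)
  one <- rep(1, q)
  sw <- drop(t(one) %*% Vi %*% one)
  P <- Vi - (Vi %*% one %*% t(one) %*% Vi) / sw
  -0.5 * (as.numeric(determinant(V)$modulus) + log(sw) +
          drop(t(y) %*% P %*% y) + (q - 1) * log(2 * pi))
}
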