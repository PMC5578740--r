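## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched. All stochastic operations in the
## package funnel through this so a single integer seed fixes a call.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a child seed from a base seed, keeping it inside 32-bit range.
childSeed <- function(seed, k) {
    if (is.null(seed)) return(NULL)
    as.integer((as.double(seed) * 1103L + as.double(k) * 7919) %% 2147483629)
}

zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
}

## Center to zero mean and scale to unit Euclidean norm.
centerUnitNorm <- function(v) {
    v <- v - mean(v)
    n <- sqrt(sum(v^2))
    if (n == 0) stop("cannot normalize an all-zero pattern")
    v / n
}

## OLS solve with explicit rank handling: returns coefficients, or stops
## naming the columns a pivoted QR would drop. Used by every regression
## surface that promises an explicit rank-deficiency error.
olsCoef <- function(X, Y, tol = 1e-10) {
    qrX <- qr(X, tol = tol)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        if (is.null(dropped)) dropped <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
        stop("design is rank deficient; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    qr.coef(qrX, Y)
}

## Mirror a value vector through a mask's left/right pairing.
mirrorValues <- function(values, mask) values[mask@pairing]
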