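# Thin-plate-spline radial basis interpolation of scattered samples.
# Exact interpolation (up to a small ridge on the kernel block) through
# f(p) = sum_i w_i phi(|p - p_i|) + a0 + a1 x + a2 y, phi(r) = r^2 log r,
# with the usual orthogonality constraints sum w = sum w x = sum w y = 0.
# Coordinates are pre-scaled by the image diagonal so the ridge is
# scale-free. Dense solve; adequate for the few-thousand-sample surfaces
# produced by dot-grid phantoms.

.tpsKernel <- function(r) {
    k <- r * r * log(r)
    k[r == 0] <- 0
    k
}

.tpsFit <- function(x, y, z, scale, ridge = 1e-8, maxCenters = 3000L) {
    n <- length(x)
    if (n > maxCenters) {
        keep <- unique(round(seq(1, n, length.out = maxCenters)))
        warning("thin-plate RBF: interpolating through ", length(keep),
            " of ", n, " samples (maxCenters)")
        x <- x[keep]; y <- y[keep]; z <- z[keep]
        n <- length(x)
    }
    xs <- x / scale; ys <- y / scale
    K <- .tpsKernel(sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2))
    P <- cbind(1, xs, ys)
    A <- rbind(cbind(K + diag(ridge, n), P),
               cbind(t(P), matrix(0, 3, 3)))
    coef <- solve(A, c(z, 0, 0, 0))
    list(type = "rbf", cx = xs, cy = ys, w = coef[seq_len(n)],
        a = coef[n + 1:3], scale = scale)
}

.tpsPredict <- function(fit, x, y, chunk = 2048L) {
    xs <- x / fit$scale; ys <- y / fit$scale
    out <- numeric(length(xs))
    for (start in seq(1, length(xs), by = chunk)) {
        i <- start:min(start + chunk - 1, length(xs))
        K <- .tpsKernel(sqrt(outer(xs[i], fit$cx, "-")^2 +
                             outer(ys[i], fit$cy, "-")^2))
        out[i] <- drop(K %*% fit$w) + fit$a[1] + fit$a[2] * xs[i] +
            fit$a[3] * ys[i]
    }
    out
}
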