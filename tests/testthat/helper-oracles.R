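# Independent brute-force oracles: plain-R enumeration implementations
# of every texture-matrix and first-order definition, kept free of the
# package's computational kernels.

# all 26 unit offsets in 3D
offsets26 <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
offsets26 <- offsets26[rowSums(abs(offsets26)) > 0, ]

# type-7 percentile by sort-and-index interpolation
oracleQuantile <- function(x, p) {
    s <- sort(x)
    n <- length(s)
    h <- (n - 1) * p / 100
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[pmin(lo + 2, n)] - s[lo + 1])
}

# normalized symmetric GLCM by exhaustive ordered-pair enumeration
oracleGlcmMatrix <- function(lev, ng, distance = 1) {
    d <- dim(lev)
    counts <- matrix(0, ng, ng)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) {
            l1 <- lev[i, j, k]
            if (l1 == 0) next
            for (o in seq_len(nrow(offsets26))) {
                ii <- i + offsets26[o, 1] * distance
                jj <- j + offsets26[o, 2] * distance
                kk <- k + offsets26[o, 3] * distance
                if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
                    kk < 1 || kk > d[3]) next
                l2 <- lev[ii, jj, kk]
                if (l2 == 0) next
                counts[l1, l2] <- counts[l1, l2] + 1
            }
        }
    counts / sum(counts)
}

oracleGlcmCorrelation <- function(p) {
    ng <- nrow(p)
    px <- rowSums(p); py <- colSums(p)
    mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
    sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
    sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
    if (sx * sy == 0) return(1)
    e <- 0
    for (i in seq_len(ng)) for (j in seq_len(ng))
        e <- e + i * j * p[i, j]
    (e - mux * muy) / (sx * sy)
}

oracleGlcmImc1 <- function(p) {
    ng <- nrow(p)
    px <- rowSums(p); py <- colSums(p)
    ent <- function(v) -sum(vapply(v, function(q)
        if (q > 0) q * log2(q) else 0, 0))
    hx <- ent(px); hy <- ent(py)
    if (max(hx, hy) == 0) return(0)
    hxy <- ent(as.numeric(p))
    hxy1 <- 0
    for (i in seq_len(ng)) for (j in seq_len(ng))
        if (p[i, j] > 0 && px[i] * py[j] > 0)
            hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j])
    (hxy - hxy1) / max(hx, hy)
}

# GLDM counts by per-voxel neighbour enumeration
oracleGldmMatrix <- function(lev, ng, alpha = 0) {
    d <- dim(lev)
    rows <- list()
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) {
            l1 <- lev[i, j, k]
            if (l1 == 0) next
            dep <- 0
            for (o in seq_len(nrow(offsets26))) {
                ii <- i + offsets26[o, 1]; jj <- j + offsets26[o, 2]
                kk <- k + offsets26[o, 3]
                if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
                    kk < 1 || kk > d[3]) next
                l2 <- lev[ii, jj, kk]
                if (l2 == 0) next
                if (abs(l2 - l1) <= alpha) dep <- dep + 1
            }
            rows[[length(rows) + 1]] <- c(l1, dep + 1)
        }
    rows <- do.call(rbind, rows)
    m <- matrix(0, ng, max(rows[, 2]))
    for (r in seq_len(nrow(rows)))
        m[rows[r, 1], rows[r, 2]] <- m[rows[r, 1], rows[r, 2]] + 1
    m
}

oracleGldmLgle <- function(m) {
    nz <- sum(m)
    acc <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
        acc <- acc + m[i, j] / i^2
    acc / nz
}

# GLSZM by recursive-free flood fill over equal-level 26-neighbours
oracleGlszmZones <- function(lev) {
    d <- dim(lev)
    seen <- array(FALSE, d)
    zones <- list()
    for (s in which(lev > 0)) {
        if (seen[s]) next
        l <- lev[s]
        queue <- s
        seen[s] <- TRUE
        size <- 0
        while (length(queue) > 0) {
            cur <- queue[1]
            queue <- queue[-1]
            size <- size + 1
            ci <- arrayInd(cur, d)
            for (o in seq_len(nrow(offsets26))) {
                nb <- ci + offsets26[o, ]
                if (any(nb < 1) || any(nb > d)) next
                lin <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
                if (!seen[lin] && lev[lin] == l) {
                    seen[lin] <- TRUE
                    queue <- c(queue, lin)
                }
            }
        }
        zones[[length(zones) + 1]] <- c(level = l, size = size)
    }
    do.call(rbind, zones)
}

oracleSznn <- function(zones) {
    nz <- nrow(zones)
    sizes <- table(zones[, "size"])
    sum(sizes^2) / nz^2
}

oracleFirstOrder <- function(v) {
    s <- sort(v)
    n <- length(s)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    m <- sum(v) / n
    m2 <- sum((v - m)^2) / n
    m3 <- sum((v - m)^3) / n
    c(Maximum = s[n], Median = med, Mean = m, Minimum = s[1],
      Range = s[n] - s[1], Variance = m2,
      Skewness = if (m2 > 0) m3 / m2^1.5 else 0, Energy = sum(v^2))
}

# AUC by exhaustive pair counting
oracleAuc <- function(scores, labels) {
    pos <- scores[labels]
    neg <- scores[!labels]
    acc <- 0
    for (p in pos) for (q in neg)
        acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
    acc / (length(pos) * length(neg))
}

# random discretized grid with a random (non-empty) mask
randomDiscretizedGrid <- function(dims = c(4, 4, 4), ng = 4,
                                  maskProb = 0.8) {
    lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
    mask <- array(runif(prod(dims)) < maskProb, dims)
    if (!any(mask)) mask[1] <- TRUE
    lev[!mask] <- 0L
    new("DiscretizedVolume", levels = lev, binWidthHu = 25,
        nLevels = as.integer(ng))
}

randomImage <- function(dims = c(6, 6, 5), spacing = c(1, 1, 2.5),
                        mean = -850, sd = 120) {
    ImageVolume(array(rnorm(prod(dims), mean, sd), dims), spacing)
}
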