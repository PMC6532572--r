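# build a small IronCountExperiment from an explicit count matrix;
# sample columns follow the canonical order genotype > condition > replicate
makeIce <- function(counts, lengths = rep(1000L, nrow(counts)),
                    nReps = NULL) {
    if (is.null(nReps)) nReps <- ncol(counts) / 4L
    g <- rep(c("wildtype", "clf"), each = 2L * nReps)
    cc <- rep(rep(c("plusFe", "minusFe"), each = nReps), 2L)
    r <- rep(seq_len(nReps), 4L)
    ids <- paste(g, cc, r, sep = "_")
    colnames(counts) <- ids
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("g", seq_len(nrow(counts)))
    IronCountExperiment(counts, lengths,
                        data.frame(sample_id = ids, genotype = g,
                                   condition = cc, replicate = r))
}

# brute-force average-linkage agglomeration over an explicit distance
# matrix; returns the sorted merge heights (oracle for hierarchicalCluster)
bruteAverageLinkHeights <- function(m) {
    d <- as.matrix(stats::dist(m))
    groups <- as.list(seq_len(nrow(m)))
    heights <- numeric(0)
    while (length(groups) > 1) {
        best <- c(NA, NA); bestd <- Inf
        for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
            dd <- mean(d[groups[[i]], groups[[j]]])
            if (dd < bestd) { bestd <- dd; best <- c(j, i) }
        }
        heights <- c(heights, bestd)
        groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
        groups[[best[2]]] <- NULL
    }
    heights
}

# exact upper-tail hypergeometric p from binomial coefficients only
# (independent of phyper)
enumHyperP <- function(k, K, N, n) {
    js <- seq(k, min(K, n))
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# hand-applied Benjamini-Hochberg step-up (oracle for bhAdjust)
stepUpBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
}
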