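#' Uncorrected p-distance with pairwise deletion
#'
#' Pairwise proportion of mismatching residues over the columns where
#' neither sequence has a gap (\code{-} or \code{.}). A Poisson
#' correction (\code{-log(1 - p)}) is available for more divergent
#' sequences; the clade logic downstream only needs relative distances,
#' so the uncorrected form is the default.
#'
#' @param aln An \linkS4class{AAStringSet} of equal-length aligned
#'   sequences (>= 2), or a named character vector.
#' @param correction \code{"none"} (p-distance, default) or
#'   \code{"poisson"}.
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @export
pDistance <- function(aln, correction = c("none", "poisson")) {
    correction <- match.arg(correction)
    if (methods::is(aln, "XStringSet")) {
        labs <- names(aln)
        seqs <- as.character(aln)
    } else {
        labs <- names(aln)
        seqs <- unname(as.character(aln))
    }
    if (length(seqs) < 2L) stop("need at least 2 sequences")
    if (is.null(labs) || any(labs == ""))
        stop("all sequences must be named")
    if (length(unique(nchar(seqs))) != 1L)
        stop("sequences must have equal aligned length")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    gap <- mat == "-" | mat == "."
    n <- nrow(mat)
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- !gap[i, ] & !gap[j, ]
        if (!any(ok))
            stop(sprintf("no comparable columns between %s and %s",
                         labs[i], labs[j]))
        p <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
        if (correction == "poisson") {
            if (p >= 1) stop("Poisson correction undefined at p >= 1")
            p <- -log(1 - p)
        }
        d[i, j] <- d[j, i] <- p
    }
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical agglomerative neighbor joining: at each step the pair
#' minimizing \eqn{Q(i,j) = (n-2) d(i,j) - \sum_k d(i,k) - \sum_k
#' d(j,k)} is joined; branch lengths follow the standard formulas
#' (negative estimates clamped to zero) and distances to the new node
#' are \eqn{(d(i,k)+d(j,k)-d(i,j))/2}. Q-ties are broken by the
#' lexicographically smallest pair of representative leaf labels, which
#' makes the result invariant to input label order. For an additive
#' matrix the tree's path lengths reproduce the input exactly (up to
#' floating-point error).
#'
#' @param dm Symmetric numeric matrix with labelled rows/columns, zero
#'   diagonal, at least 3 labels.
#' @return Unrooted \code{ape} \code{phylo} tree.
#' @export
njTree <- function(dm) {
    if (!is.matrix(dm) || is.null(rownames(dm)))
        stop("dm must be a labelled matrix")
    if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12,
                          check.attributes = FALSE)))
        stop("distance matrix must be symmetric")
    labs <- rownames(dm)
    if (length(labs) < 3L) stop("neighbor joining needs >= 3 labels")
    # canonical label order makes tie-breaking permutation-invariant
    o <- order(labs)
    d <- dm[o, o, drop = FALSE]
    nwk <- rownames(d)             # newick fragment per active node
    rep <- rownames(d)             # smallest descendant leaf label
    while (nrow(d) > 3L) {
        n <- nrow(d)
        r <- rowSums(d)
        q <- (n - 2) * d - outer(r, r, `+`)
        diag(q) <- Inf
        qmin <- min(q)
        cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        keypair <- apply(cand, 1L, function(ij) {
            pr <- sort(c(rep[ij[1L]], rep[ij[2L]]))
            paste(pr, collapse = "\r")
        })
        pick <- cand[order(keypair)[1L], ]
        i <- pick[1L]; j <- pick[2L]
        li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
        lj <- d[i, j] - li
        li <- max(0, li); lj <- max(0, lj)
        newNwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], li, nwk[j], lj)
        newRep <- min(rep[i], rep[j])
        dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
        keep <- setdiff(seq_len(n), c(i, j))
        d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                    c(dn[keep], 0))
        nwk <- c(nwk[keep], newNwk)
        rep <- c(rep[keep], newRep)
        rownames(d2) <- colnames(d2) <- rep
        d <- d2
    }
    la <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    lb <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    lc <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    s <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk[1L], la, nwk[2L], lb, nwk[3L], lc)
    ape::read.tree(text = s)
}

.tipsUnder <- function(tree, node) {
    ntip <- length(tree$tip.label)
    if (node <= ntip) return(tree$tip.label[node])
    out <- character()
    stack <- node
    while (length(stack)) {
        nd <- stack[[1L]]; stack <- stack[-1L]
        kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
        tips <- kids[kids <= ntip]
        out <- c(out, tree$tip.label[tips])
        stack <- c(stack, kids[kids > ntip])
    }
    out
}

#' Type one query leaf by outgroup-rooted clade membership
#'
#' Operationalizes "clustered with" on a per-query tree: the tree is
#' rooted on the outgroup (on the edge above the outgroup clade when
#' several outgroup leaves are present), then ancestors of the query
#' are visited from the tip upwards and the first clade containing any
#' non-query labelled leaf decides the call. A clade of only xoxF
#' references calls xoxF; only mxaF references, mxaF; a clade that
#' contains an outgroup leaf (the query attaches within or sister to
#' the outgroup) or references of both types is undetermined.
#'
#' @param tree Unrooted \code{phylo} tree whose tips are the query, the
#'   references and the outgroup(s).
#' @param roles Named character vector label -> role, roles in
#'   \code{query}, \code{ref_xoxF}, \code{ref_mxaF}, \code{outgroup}.
#' @return List with \code{query} (label) and \code{call} (one of
#'   \code{"xoxF"}, \code{"mxaF"}, \code{"undetermined"}).
#' @export
typeQuery <- function(tree, roles) {
    stopifnot(inherits(tree, "phylo"))
    roles <- roles[tree$tip.label]
    qlab <- names(roles)[roles == "query"]
    if (length(qlab) != 1L) stop("exactly one query leaf is required")
    ogs <- names(roles)[roles == "outgroup"]
    if (length(ogs) == 0L) stop("an outgroup leaf is required for rooting")
    rooted <- tryCatch(ape::root(tree, outgroup = ogs, resolve.root = TRUE),
                       error = function(e)
                           ape::root(tree, outgroup = ogs[1L],
                                     resolve.root = TRUE))
    ntip <- length(rooted$tip.label)
    qtip <- match(qlab, rooted$tip.label)
    node <- rooted$edge[rooted$edge[, 2L] == qtip, 1L]
    call <- "undetermined"
    repeat {
        tips <- setdiff(.tipsUnder(rooted, node), qlab)
        if (length(tips)) {
            rr <- roles[tips]
            if (any(rr == "outgroup")) { call <- "undetermined"; break }
            refTypes <- unique(rr[rr %in% c("ref_xoxF", "ref_mxaF")])
            if (length(refTypes) == 1L) {
                call <- sub("^ref_", "", refTypes)
                break
            }
            if (length(refTypes) > 1L) { call <- "undetermined"; break }
        }
        up <- rooted$edge[rooted$edge[, 2L] == node, 1L]
        if (length(up) == 0L) { call <- "undetermined"; break }
        node <- up
    }
    list(query = qlab, call = call)
}

#' Type every query, one tree per query
#'
#' Builds, for each query, a tree over that query plus all references
#' and outgroups (queries are near-random fragments; a joint tree over
#' all of them is typically unresolvable, so each is placed on its
#' own), then applies \code{\link{typeQuery}}.
#'
#' @param aln An equal-length aligned \linkS4class{AAStringSet} (or
#'   named character vector) containing queries, references and
#'   outgroups.
#' @param roles Named character vector label -> role as in
#'   \code{\link{typeQuery}}.
#' @param correction Distance correction passed to
#'   \code{\link{pDistance}}.
#' @return List with \code{calls} (data.frame query/call) and
#'   \code{counts} (table over xoxF/mxaF/undetermined).
#' @export
typeAll <- function(aln, roles, correction = "none") {
    seqs <- stats::setNames(as.character(aln), names(aln))
    missing <- setdiff(names(roles), names(seqs))
    if (length(missing))
        stop("roles refer to absent sequence(s): ",
             paste(missing, collapse = ", "))
    queries <- names(roles)[roles == "query"]
    refs <- names(roles)[roles %in% c("ref_xoxF", "ref_mxaF")]
    ogs <- names(roles)[roles == "outgroup"]
    if (!any(roles == "ref_xoxF") || !any(roles == "ref_mxaF"))
        stop("need at least one reference of each type")
    if (length(ogs) == 0L) stop("need at least one outgroup")
    calls <- lapply(queries, function(q) {
        sub <- seqs[c(q, refs, ogs)]
        d <- pDistance(sub, correction = correction)
        typeQuery(njTree(d), roles[c(q, refs, ogs)])
    })
    df <- data.frame(
        query = vapply(calls, `[[`, character(1L), "query"),
        call = vapply(calls, `[[`, character(1L), "call"),
        stringsAsFactors = FALSE)
    counts <- table(factor(df$call,
                           levels = c("xoxF", "mxaF", "undetermined")))
    list(calls = df, counts = counts)
}

#' Read a label-to-role sidecar TSV
#'
#' Two tab-separated columns (label, role), no header; roles restricted
#' to \code{query}, \code{ref_xoxF}, \code{ref_mxaF}, \code{outgroup}.
#'
#' @param path Path to the TSV.
#' @return Named character vector label -> role.
#' @export
readRoles <- function(path) {
    df <- utils::read.delim(path, header = FALSE,
                            col.names = c("label", "role"),
                            stringsAsFactors = FALSE)
    ok <- c("query", "ref_xoxF", "ref_mxaF", "outgroup")
    bad <- setdiff(unique(df$role), ok)
    if (length(bad))
        stop("unsupported role(s): ", paste(bad, collapse = ", "))
    stats::setNames(df$role, df$label)
}
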