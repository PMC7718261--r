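#' Full-rank PCA with a deterministic sign convention
#'
#' Principal components of a samples x features matrix (features centered,
#' not rescaled: inputs are already z-scored gene expression or PC scores).
#' As many PCs as input features are produced (capped by the sample count).
#' Each PC's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param X numeric matrix, samples in rows.
#' @return list(rotation, center, sdev, scores, explained).
#' @export
pcaFit <- function(X) {
    X <- as.matrix(X)
    if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    rot <- pr$rotation
    for (j in seq_len(ncol(rot))) {
        i0 <- which.max(abs(rot[, j]))
        if (rot[i0, j] < 0) rot[, j] <- -rot[, j]
    }
    scores <- sweep(X, 2L, pr$center) %*% rot
    ev <- pr$sdev^2
    list(rotation = rot, center = pr$center, sdev = pr$sdev,
         scores = scores, explained = ev / sum(ev))
}

#' Screen principal components with a random forest
#'
#' A 1000-tree classification forest is trained on the binary progression
#' indicator; "percent contribution" of each PC is its impurity-decrease
#' importance normalized to sum to 1 (permutation importance by option).
#' PCs with contribution above the cutoff are kept; if none clears it, the
#' single top PC is kept so the selection is never empty.
#'
#' @param pcScores samples x PCs score matrix.
#' @param labels binary vector, both classes present.
#' @param nTrees number of trees (default 1000).
#' @param cutoff contribution cutoff (default 0.05).
#' @param seed RNG seed for the forest.
#' @param importance \code{"impurity"} (default) or \code{"permutation"}.
#' @return list(selected = PC indices, contribution = per-PC share).
#' @export
rfScreenPcs <- function(pcScores, labels, nTrees = 1000L, cutoff = 0.05,
                        seed = 1L, importance = c("impurity",
                                                  "permutation")) {
    importance <- match.arg(importance)
    y <- factor(.checkBinary(labels))
    pcScores <- as.matrix(pcScores)
    colnames(pcScores) <- paste0("PC", seq_len(ncol(pcScores)))
    rf <- .withSeed(seed,
        randomForest::randomForest(x = pcScores, y = y, ntree = nTrees,
                                   importance = importance == "permutation"))
    imp <- if (importance == "permutation")
        pmax(randomForest::importance(rf, type = 1L)[, 1L], 0)
    else randomForest::importance(rf, type = 2L)[, 1L]
    contribution <- if (sum(imp) > 0) imp / sum(imp)
        else rep(1 / length(imp), length(imp))
    selected <- which(contribution > cutoff)
    if (!length(selected)) selected <- which.max(contribution)
    list(selected = as.integer(selected),
         contribution = unname(contribution))
}

#' Iterate PCA and random-forest PC screening
#'
#' Alternates \code{\link{pcaFit}} on the current representation with
#' \code{\link{rfScreenPcs}}, feeding the selected PC scores into the next
#' PCA, until the forest retains every current PC (or \code{maxRounds} is
#' hit, with a warning). Every round's rotation, center and selected indices
#' are recorded so the exact transformation can be replayed on new samples.
#'
#' @param X samples x features matrix (z-scored signature expression).
#' @param labels binary progression indicator.
#' @param maxRounds iteration cap (default 10).
#' @param nTrees,cutoff,importance forest parameters.
#' @param seed pipeline seed; round r uses seed + r for its forest.
#' @return list(stack, finalScores, converged, rounds).
#' @export
iteratePcaRf <- function(X, labels, maxRounds = 10L, nTrees = 1000L,
                         cutoff = 0.05, seed = 1L,
                         importance = "impurity") {
    current <- as.matrix(X)
    stack <- list()
    converged <- FALSE
    for (r in seq_len(maxRounds)) {
        p <- pcaFit(current)
        sel <- rfScreenPcs(p$scores, labels, nTrees = nTrees,
                           cutoff = cutoff, seed = seed + r,
                           importance = importance)
        stack[[r]] <- list(rotation = p$rotation, center = p$center,
                           selected = sel$selected,
                           contribution = sel$contribution)
        current <- p$scores[, sel$selected, drop = FALSE]
        if (length(sel$selected) == ncol(p$scores)) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("PCA/RF iteration did not converge in ", maxRounds,
                " rounds; using the representation after the last round")
    list(stack = stack, finalScores = current, converged = converged,
         rounds = length(stack))
}

# replay a recorded PCA/RF stack on a samples x genes z-score matrix
.replayPcaStack <- function(Z, stack) {
    cur <- as.matrix(Z)
    for (s in stack) {
        sc <- sweep(cur, 2L, s$center) %*% s$rotation
        cur <- sc[, s$selected, drop = FALSE]
    }
    cur
}

# --- boosted ensemble of small tanh networks -------------------------------

# extract weights from an nnet fit (d inputs, h logistic hidden units,
# linear output) and convert exactly to the tanh parametrization:
# sigma(a) = (tanh(a/2) + 1)/2, so
#   b2 + sum_j w2_j * sigma(a_j) = [b2 + sum_j w2_j/2] + sum_j (w2_j/2) tanh(a_j/2)
.nnetToTanh <- function(fit, d, h) {
    w <- fit$wts
    W1 <- matrix(0, h, d)
    b1 <- numeric(h)
    for (j in seq_len(h)) {
        blk <- w[((j - 1L) * (d + 1L) + 1L):(j * (d + 1L))]
        b1[j] <- blk[1L]
        W1[j, ] <- blk[-1L]
    }
    outBlk <- w[(h * (d + 1L) + 1L):(h * (d + 1L) + h + 1L)]
    b2 <- outBlk[1L]
    w2 <- outBlk[-1L]
    list(W1 = W1 / 2, b1 = b1 / 2, w2 = w2 / 2, b2 = b2 + sum(w2) / 2)
}

# forward pass of one tanh weak learner on samples x d matrix
.tanhNetPredict <- function(net, X) {
    A <- tanh(sweep(X %*% t(net$W1), 2L, net$b1, `+`))
    drop(A %*% net$w2) + net$b2
}

# train one boosted ensemble on the full data given; returns intercept +
# list of weak learners (each with its accepted step size)
.trainBoostedEnsemble <- function(P, y, stages, hidden, lr, maxit = 100L) {
    P <- as.matrix(P)
    d <- ncol(P)
    pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
    F0 <- stats::qlogis(pbar)
    Fcur <- rep(F0, length(y))
    ens <- vector("list", stages)
    for (m in seq_len(stages)) {
        resid <- y - stats::plogis(Fcur)   # negative gradient of log-loss
        fit <- nnet::nnet(x = P, y = resid, size = hidden, linout = TRUE,
                          trace = FALSE, maxit = maxit, decay = 1e-4)
        net <- .nnetToTanh(fit, d, hidden)
        pred <- .tanhNetPredict(net, P)
        # step-halving guard keeps the training log-loss non-increasing
        step <- lr
        base <- .logloss(y, Fcur)
        for (tries in 1:12) {
            if (.logloss(y, Fcur + step * pred) <= base + 1e-12) break
            step <- step / 2
            if (tries == 12L) step <- 0
        }
        net$step <- step
        ens[[m]] <- net
        Fcur <- Fcur + step * pred
    }
    list(intercept = F0, ensemble = ens)
}

.predictBoosted <- function(intercept, ensemble, P) {
    P <- as.matrix(P)
    Fcur <- rep(intercept, nrow(P))
    for (net in ensemble)
        if (net$step != 0)
            Fcur <- Fcur + net$step * .tanhNetPredict(net, P)
    stats::plogis(Fcur)
}

#' Fit the boosted tanh-network classifier
#'
#' Gradient boosting on the log-odds scale: the model starts from the
#' intercept log-odds of the class balance and, for 100 stages, fits a
#' 1-hidden-layer network with 3 tanh units (linear output) to the
#' negative-gradient pseudo-residuals of the log-loss, adding it with
#' learning rate 0.1 (with step-halving if a stage would increase the
#' training log-loss). Tenfold stratified cross-validation produces
#' out-of-fold probabilities for honest AUC; the deployed ensemble is refit
#' on all samples.
#'
#' @param P samples x PCs matrix (the final PC set).
#' @param labels binary progression indicator.
#' @param stages boosting stages (default 100).
#' @param hidden hidden tanh units per weak learner (default 3).
#' @param lr learning rate (default 0.1).
#' @param folds CV folds (default 10); needs at least \code{folds} samples
#'   in each class.
#' @param seed RNG seed (weak-learner initialization and fold assignment).
#' @param maxit optimizer iterations per weak learner.
#' @return list(intercept, ensemble, oofProb, foldAssign, aucOof).
#' @export
fitBoostedNet <- function(P, labels, stages = 100L, hidden = 3L, lr = 0.1,
                          folds = 10L, seed = 1L, maxit = 100L) {
    P <- as.matrix(P)
    y <- .checkBinary(labels)
    if (min(table(y)) < folds)
        stop("need at least ", folds, " samples per class for ", folds,
             "-fold stratified CV")
    foldAssign <- .stratifiedFolds(y, folds, seed)
    oof <- rep(NA_real_, length(y))
    for (k in seq_len(folds)) {
        tr <- foldAssign != k
        mod <- .withSeed(seed + 1000L + k,
            .trainBoostedEnsemble(P[tr, , drop = FALSE], y[tr], stages,
                                  hidden, lr, maxit))
        oof[!tr] <- .predictBoosted(mod$intercept, mod$ensemble,
                                    P[!tr, , drop = FALSE])
    }
    final <- .withSeed(seed,
        .trainBoostedEnsemble(P, y, stages, hidden, lr, maxit))
    list(intercept = final$intercept, ensemble = final$ensemble,
         oofProb = oof, foldAssign = foldAssign,
         aucOof = rocAuc(oof, y)$auc)
}

#' Train the full risk-scoring pipeline on a cohort
#'
#' Z-scores the signature genes on the training cohort (recording the
#' per-gene normalization), runs the iterated PCA / random-forest PC
#' screen, and fits the boosted tanh-network classifier with tenfold CV.
#'
#' @param x a \linkS4class{PgsExperiment} (raw or log scale).
#' @param signature a \linkS4class{Signature} (or character vector of genes).
#' @param labels binary progression indicator; default column
#'   \code{progressed} of the clinical data. NA-labelled samples are
#'   excluded from training.
#' @param seed single pipeline seed driving forest, folds and net
#'   initialization.
#' @param nTrees,cutoff,importance,maxRounds PC-screening parameters.
#' @param stages,hidden,lr,folds,maxit boosting parameters.
#' @return A \linkS4class{RiskModel}.
#' @export
trainRiskModel <- function(x, signature, labels = NULL, seed = 1L,
                           nTrees = 1000L, cutoff = 0.05,
                           importance = "impurity", maxRounds = 10L,
                           stages = 100L, hidden = 3L, lr = 0.1,
                           folds = 10L, maxit = 100L) {
    if (is.character(signature))
        signature <- methods::new("Signature", label = "", genes = signature,
                                  stepwiseP = stats::setNames(
                                      rep(NA_real_, length(signature)),
                                      signature),
                                  modelBIC = NA_real_,
                                  trace = data.frame())
    genes <- signature@genes
    if (!length(genes)) stop("signature has no genes")
    miss <- setdiff(genes, rownames(x))
    if (length(miss))
        stop("signature gene(s) absent from matrix: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    if (is.null(labels)) labels <- clinicalData(x)$progressed
    if (!is.null(names(labels))) labels <- labels[colnames(x)]
    keep <- !is.na(labels)
    xs <- x[genes, keep]
    z <- zscoreByGene(xs)
    y <- .checkBinary(labels[keep])
    Z <- t(exprValues(z))

    it <- iteratePcaRf(Z, y, maxRounds = maxRounds, nTrees = nTrees,
                       cutoff = cutoff, seed = seed, importance = importance)
    bn <- fitBoostedNet(it$finalScores, y, stages = stages, hidden = hidden,
                        lr = lr, folds = folds, seed = seed, maxit = maxit)
    methods::new("RiskModel",
                 signature = signature,
                 geneNorm = metadata(z)$geneNorm,
                 pcaStack = it$stack,
                 forestSpec = list(nTrees = nTrees, cutoff = cutoff,
                                   importance = importance, seed = seed,
                                   converged = it$converged,
                                   rounds = it$rounds),
                 ensemble = bn$ensemble,
                 intercept = bn$intercept,
                 learningRate = lr,
                 cvSpec = list(folds = folds, seed = seed,
                               foldAssign = bn$foldAssign),
                 oof = data.frame(sample_id = colnames(xs),
                                  probability = bn$oofProb,
                                  stringsAsFactors = FALSE),
                 trainingAucOof = bn$aucOof)
}

#' Score samples with a trained risk model
#'
#' Normalizes the signature genes (either by replaying the training
#' per-gene (mean, sd) -- appropriate for same-platform samples -- or by
#' z-scoring within the scored cohort, the protocol for cross-platform
#' validation cohorts), replays the recorded PCA/RF stack, applies the
#' boosted ensemble, and maps the probability p to the risk score
#' 100 * (p - 0.5) in [-50, 50]. Scores above 0 are the high-risk group;
#' 0 and below are low-risk. More than 20\% missing signature genes is an
#' error; up to 20\% are imputed at z = 0 with per-gene warnings.
#'
#' @param model a \linkS4class{RiskModel}.
#' @param x a \linkS4class{PgsExperiment} to score.
#' @param normalization \code{"replay"} (default) or \code{"cohort"}.
#' @return data.frame (sample_id, probability, score, group).
#' @export
scoreSamples <- function(model, x, normalization = c("replay", "cohort")) {
    normalization <- match.arg(normalization)
    genes <- model@signature@genes
    present <- intersect(genes, rownames(x))
    missing <- setdiff(genes, present)
    if (length(missing) / length(genes) > 0.2)
        stop("more than 20% of signature genes missing from matrix (",
             length(missing), "/", length(genes), ")")
    for (g in missing)
        warning("signature gene '", g, "' missing; imputed at z = 0")

    if (exprScale(x) == "zscore") {
        zmat <- exprValues(x)[present, , drop = FALSE]
    } else if (normalization == "replay") {
        zx <- applyGeneNorm(x, model@geneNorm)
        zmat <- exprValues(zx)[intersect(present, rownames(zx)), ,
                               drop = FALSE]
    } else {
        zx <- zscoreByGene(x[present, ])
        zmat <- exprValues(zx)
    }
    Z <- matrix(0, ncol(x), length(genes),
                dimnames = list(colnames(x), genes))
    Z[, rownames(zmat)] <- t(zmat)
    P <- .replayPcaStack(Z, model@pcaStack)
    prob <- .predictBoosted(model@intercept, model@ensemble, P)
    score <- 100 * (prob - 0.5)
    data.frame(sample_id = colnames(x),
               probability = prob,
               score = score,
               group = ifelse(score > 0, "high", "low"),
               stringsAsFactors = FALSE)
}

# --- model serialization ---------------------------------------------------

#' Serialize a risk model to JSON
#'
#' All numeric content is written at full precision, so reading the file
#' back and rescoring reproduces scores to within 1e-10.
#'
#' @param model a \linkS4class{RiskModel}.
#' @param path output path.
#' @export
writeRiskModel <- function(model, path) {
    obj <- list(
        format = "progsig-risk-model-v1",
        signature = list(label = model@signature@label,
                         genes = model@signature@genes,
                         stepwiseP = unname(model@signature@stepwiseP),
                         modelBIC = model@signature@modelBIC),
        geneNorm = model@geneNorm,
        pcaStack = lapply(model@pcaStack, function(s)
            list(rotation = s$rotation, center = s$center,
                 selected = s$selected, contribution = s$contribution)),
        forestSpec = model@forestSpec,
        ensemble = lapply(model@ensemble, function(n)
            list(W1 = n$W1, b1 = n$b1, w2 = n$w2, b2 = n$b2,
                 step = n$step)),
        intercept = model@intercept,
        learningRate = model@learningRate,
        cvSpec = model@cvSpec,
        oof = model@oof,
        trainingAucOof = model@trainingAucOof)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor", na = "null")
    invisible(path)
}

#' Read a risk model from JSON
#' @param path path written by \code{\link{writeRiskModel}}.
#' @return A \linkS4class{RiskModel}.
#' @export
readRiskModel <- function(path) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(o$format, "progsig-risk-model-v1"))
        stop("'", path, "' is not a progsig risk model file")
    num <- function(v, n = 1L) {       # JSON null -> NA
        if (is.null(v) || !length(v)) rep(NA_real_, n)
        else vapply(v, function(e) if (is.null(e)) NA_real_
                    else as.numeric(e), numeric(1))
    }
    sigGenes <- as.character(unlist(o$signature$genes))
    sig <- methods::new("Signature", label = o$signature$label,
                        genes = sigGenes,
                        stepwiseP = stats::setNames(
                            num(o$signature$stepwiseP, length(sigGenes)),
                            sigGenes),
                        modelBIC = num(o$signature$modelBIC),
                        trace = data.frame())
    # jsonlite simplifies the stack entries differently depending on shape
    # homogeneity; re-read without simplification for robustness
    o2 <- jsonlite::read_json(path, simplifyVector = FALSE)
    stack <- lapply(o2$pcaStack, function(s) {
        rot <- do.call(rbind, lapply(s$rotation, function(r)
            as.numeric(unlist(r))))
        list(rotation = rot, center = as.numeric(unlist(s$center)),
             selected = as.integer(unlist(s$selected)),
             contribution = as.numeric(unlist(s$contribution)))
    })
    ens <- lapply(o2$ensemble, function(n) {
        W1 <- do.call(rbind, lapply(n$W1, function(r) as.numeric(unlist(r))))
        list(W1 = W1, b1 = as.numeric(unlist(n$b1)),
             w2 = as.numeric(unlist(n$w2)), b2 = as.numeric(n$b2),
             step = as.numeric(n$step))
    })
    gn <- as.data.frame(o$geneNorm)
    rownames(gn) <- gn$gene
    methods::new("RiskModel", signature = sig, geneNorm = gn,
                 pcaStack = stack,
                 forestSpec = as.list(o$forestSpec),
                 ensemble = ens,
                 intercept = num(o$intercept),
                 learningRate = num(o$learningRate),
                 cvSpec = as.list(o$cvSpec),
                 oof = as.data.frame(o$oof),
                 trainingAucOof = num(o$trainingAucOof))
}
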