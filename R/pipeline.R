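#' @include gflasso.R
NULL

## canonical 14-step GFlasso pipeline (names and order are fixed)
.stepTable <- function() {
  data.frame(
    index = 1:14,
    name = c("Lasso stage 1", "Lasso validation error", "Lasso stage 2",
             "Lasso validation error", "Marker Processing",
             "Connected component analysis", "Spectral clustering",
             "Trait Processing", "GFlasso stage 1",
             "GFlasso validation error stage 1", "GFlasso stage 2",
             "GFlasso validation error stage 2", "GFlasso stage 3",
             "GFlasso validation error stage 3"),
    stage = c(rep("Preprocessing SNPs", 5), rep("Preprocessing traits", 3),
              rep("GFlasso optimization", 6)),
    stringsAsFactors = FALSE
  )
}

#' Pipeline configuration
#'
#' Collects the tunable constants of the 14-step GFlasso pipeline. The
#' defaults are the operational constants of the pipeline design: trait
#' blocks of 250 (the largest trait set one GFlasso problem handles), a
#' marker cap of 4000 after lasso prescreening, correlation tiles of 1000
#' traits, 5-fold lasso and 10-fold GFlasso cross-validation.
#'
#' @param traitBlock sub-network / trait-job size cap.
#' @param markerCap markers passed from lasso prescreening to GFlasso.
#' @param correlationSection tile width of the correlation computation.
#' @param networkThreshold absolute-correlation edge threshold.
#' @param lambdaGrid,gammaGrid optional explicit GFlasso scan grids; when
#'   `NULL` they default to `gridPoints` log-spaced values over
#'   `[0.01, 1]` (lambda) and `[0.01, 10]` (gamma) times the data's critical
#'   sparsity scale `max |X'Y|`.
#' @param gridPoints size of the default grids.
#' @param lassoFolds,gflassoFolds cross-validation folds (5 and 10).
#' @param nWorkers parallel workers for within-step jobs; results are
#'   independent of this value.
#' @param seed master seed; every stochastic element (fold splits, k-means
#'   initialization) derives from it via a fixed per-step offset.
#' @param tol,mu,maxIter GFlasso solver controls used during the search
#'   (`mu = 1e-3` is CV-grade accuracy; see [gflassoProblem()]).
#' @param cvMode `"cv"` or `"random"`, see [cvErrorGFlasso()].
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(traitBlock = 250L, markerCap = 4000L,
                           correlationSection = 1000L, networkThreshold = 0.5,
                           lambdaGrid = NULL, gammaGrid = NULL,
                           gridPoints = 10L, lassoFolds = 5L,
                           gflassoFolds = 10L, nWorkers = 1L, seed = 1L,
                           tol = 1e-4, mu = 1e-3, maxIter = 10000L,
                           cvMode = "cv") {
  cfg <- list(traitBlock = as.integer(traitBlock),
              markerCap = as.integer(markerCap),
              correlationSection = as.integer(correlationSection),
              networkThreshold = as.numeric(networkThreshold),
              lambdaGrid = lambdaGrid, gammaGrid = gammaGrid,
              gridPoints = as.integer(gridPoints),
              lassoFolds = as.integer(lassoFolds),
              gflassoFolds = as.integer(gflassoFolds),
              nWorkers = as.integer(nWorkers), seed = as.integer(seed),
              tol = as.numeric(tol), mu = as.numeric(mu),
              maxIter = as.integer(maxIter), cvMode = cvMode,
              failAt = NA_integer_)
  if (cfg$traitBlock < 1L || cfg$markerCap < 1L || cfg$correlationSection < 1L)
    gfStop("gfmap_spec_error", "caps must be >= 1")
  if (cfg$lassoFolds < 2L || cfg$gflassoFolds < 2L)
    gfStop("gfmap_spec_error", "folds must be >= 2")
  class(cfg) <- "PipelineConfig"
  cfg
}

stepSeed <- function(seed, step, job = 0L) {
  as.integer((as.numeric(seed) + 1009 * step + 9176 * job) %% 2147483647)
}

manifestPath <- function(workspace) file.path(workspace, "manifest.json")
artifactDir <- function(workspace) file.path(workspace, "artifacts")
artifactPath <- function(workspace, name)
  file.path(artifactDir(workspace), paste0(name, ".rds"))

saveManifest <- function(m) {
  obj <- list(seed = m@seed, config = m@config[setdiff(names(m@config), "class")],
              steps = m@steps)
  jsonlite::write_json(obj, manifestPath(m@workspace), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(m)
}

#' Load a pipeline manifest from its workspace
#'
#' @param workspace the workspace directory.
#' @return the \linkS4class{PipelineManifest}.
#' @export
loadManifest <- function(workspace) {
  obj <- jsonlite::read_json(manifestPath(workspace), simplifyVector = TRUE)
  steps <- as.data.frame(obj$steps, stringsAsFactors = FALSE)
  steps$index <- as.integer(steps$index)
  steps$n_jobs <- as.integer(steps$n_jobs)
  steps$jobs_done <- as.integer(steps$jobs_done)
  cfg <- obj$config
  cfg$lambdaGrid <- if (length(cfg$lambdaGrid)) as.numeric(cfg$lambdaGrid) else NULL
  cfg$gammaGrid <- if (length(cfg$gammaGrid)) as.numeric(cfg$gammaGrid) else NULL
  # NA_integer_ serializes to the string "NA"; restore the typed NA
  cfg$failAt <- suppressWarnings(as.integer(cfg$failAt))
  if (!length(cfg$failAt)) cfg$failAt <- NA_integer_
  class(cfg) <- "PipelineConfig"
  new("PipelineManifest", steps = steps, config = cfg,
      seed = as.integer(obj$seed), workspace = workspace)
}

#' Build the 14-step GFlasso pipeline manifest
#'
#' Validates and stores the paired input data in the workspace (the only
#' point where input data are read; results are written only by the final
#' step) and creates the ordered 14-step manifest, all steps pending.
#'
#' @param pd a \linkS4class{PairedDataset} (already validated by the import
#'   functions).
#' @param config a [pipelineConfig()].
#' @param workspace directory for the manifest, checkpoints and results
#'   (created if needed).
#' @return a \linkS4class{PipelineManifest}.
#' @export
buildManifest <- function(pd, config, workspace) {
  stopifnot(is(pd, "PairedDataset"), inherits(config, "PipelineConfig"))
  validObject(pd)
  dir.create(artifactDir(workspace), recursive = TRUE, showWarnings = FALSE)
  saveRDS(pd, file.path(workspace, "input.rds"))
  steps <- .stepTable()
  steps$status <- "pending"
  steps$n_jobs <- 0L
  steps$jobs_done <- 0L
  steps$artifact <- ""
  steps$error <- ""
  steps$started <- ""
  steps$finished <- ""
  m <- new("PipelineManifest", steps = steps, config = config,
           seed = config$seed, workspace = workspace)
  saveManifest(m)
  m
}

## ---- internal step machinery -----------------------------------------------

loadArtifact <- function(ws, name) readRDS(artifactPath(ws, name))

## run a list of job thunks with per-job checkpointing and optional forking;
## returns the list of job results in job order
runJobs <- function(ws, step, jobs, nWorkers) {
  jobFile <- function(j) artifactPath(ws, sprintf("step%02d_job%03d", step, j))
  todo <- which(!file.exists(vapply(seq_along(jobs), jobFile, "")))
  if (length(todo)) {
    worker <- function(j) {
      res <- jobs[[j]]()
      saveRDS(res, jobFile(j))
      TRUE
    }
    if (nWorkers > 1L && .Platform$OS.type == "unix") {
      out <- parallel::mclapply(todo, worker, mc.cores = nWorkers)
      bad <- vapply(out, inherits, TRUE, "try-error")
      if (any(bad)) stop(attr(out[[which(bad)[1]]], "condition")$message)
    } else {
      lapply(todo, worker)
    }
  }
  lapply(seq_along(jobs), function(j) readRDS(jobFile(j)))
}

## standardize the selected-marker matrix and center the trait block the way
## the GFlasso objective expects (no intercept)
standardizeForGFlasso <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- sqrt(colSums(Xc^2) / nrow(X))
  s[s == 0] <- 1
  list(X = sweep(Xc, 2L, s, "/"), scale = s)
}

defaultGFGrid <- function(scale, lo, hi, nPoints)
  exp(seq(log(hi * scale), log(lo * scale), length.out = nPoints))

## per-(block, fold) CV errors over a scan grid; the job unit of steps 9/11/13
gfGridJob <- function(block, testIdx, grid, varying, fixed, cfg) {
  X <- block$X; Y <- block$Y
  Xtr <- X[-testIdx, , drop = FALSE]; Ytr <- Y[-testIdx, , drop = FALSE]
  Xte <- X[testIdx, , drop = FALSE]; Yte <- Y[testIdx, , drop = FALSE]
  warm <- NULL
  errs <- numeric(length(grid))
  for (i in seq_along(grid)) {
    lam <- if (varying == "lambda") grid[i] else fixed
    gam <- if (varying == "gamma") grid[i] else fixed
    prob <- gflassoProblem(Xtr, Ytr, block$edges, lam, gam, mu = cfg$mu,
                           tol = cfg$tol, maxIter = cfg$maxIter)
    sol <- fitGFlasso(prob, warmStart = warm)
    warm <- sol@B
    errs[i] <- sum((Yte - Xte %*% sol@B)^2)
  }
  errs
}

gfTestSets <- function(n, cfg, stageStep) {
  if (cfg$cvMode == "cv") {
    f <- makeFolds(n, cfg$gflassoFolds, stepSeed(cfg$seed, stageStep))
    lapply(sort(unique(f)), function(i) which(f == i))
  } else {
    set.seed(stepSeed(cfg$seed, stageStep))
    lapply(seq_len(cfg$gflassoFolds),
           function(i) sample.int(n, max(1L, round(0.1 * n))))
  }
}

## one GFlasso scan stage (steps 9, 11, 13): jobs = sub-network x fold
runGFScan <- function(ws, step, cfg, grid, varying, fixed) {
  blocks <- loadArtifact(ws, "blocks")
  n <- nrow(blocks[[1]]$X)
  testSets <- gfTestSets(n, cfg, step)
  jobSpec <- expand.grid(block = seq_along(blocks), fold = seq_along(testSets))
  jobs <- lapply(seq_len(nrow(jobSpec)), function(i) {
    b <- jobSpec$block[i]; f <- jobSpec$fold[i]
    force(b); force(f)
    function() gfGridJob(blocks[[b]], testSets[[f]], grid, varying, fixed, cfg)
  })
  res <- runJobs(ws, step, jobs, cfg$nWorkers)
  errs <- Reduce(`+`, res)  # summed over folds and blocks
  list(grid = grid, varying = varying, fixed = fixed, cvError = errs,
       nJobs = length(jobs))
}

pickBest <- function(errs) as.integer(which(errs == min(errs))[1L])

## ---- the 14 step implementations -------------------------------------------

executeStep <- function(m, step) {
  ws <- m@workspace
  cfg <- m@config
  if (!is.na(cfg$failAt) && cfg$failAt == step)
    stop(sprintf("injected failure at step %d", step))
  pd <- readRDS(file.path(ws, "input.rds"))
  X <- pd@genotype@values
  Y <- pd@traits@values
  n <- nrow(X)
  save <- function(name, value) {
    saveRDS(value, artifactPath(ws, name))
    name
  }
  switch(as.character(step),
    "1" = {  # Lasso stage 1: coarse lambda CV over trait blocks
      grid <- sort(unique(defaultLambdaGrid(pd, cfg$gridPoints)), decreasing = TRUE)
      folds <- makeFolds(n, cfg$lassoFolds, stepSeed(cfg$seed, 1L))
      bounds <- chunkBounds(ncol(Y), cfg$traitBlock)
      jobs <- lapply(seq_len(nrow(bounds)), function(b) {
        force(b)
        function() lassoCVBlock(X, Y[, bounds$start[b]:bounds$end[b],
                                     drop = FALSE], grid, folds)
      })
      res <- runJobs(ws, 1L, jobs, cfg$nWorkers)
      list(artifact = save("lasso_stage1", list(grid = grid, folds = folds,
                                                errs = res)),
           nJobs = length(jobs))
    },
    "2" = {  # combine stage-1 errors, pick the coarse best lambda
      s1 <- loadArtifact(ws, "lasso_stage1")
      cvError <- Reduce(`+`, s1$errs)
      state <- new("LambdaSearchState", grid = s1$grid, cvError = cvError,
                   bestIndex = pickBest(cvError), stage = "coarse")
      list(artifact = save("lasso_state1", state), nJobs = 1L)
    },
    "3" = {  # Lasso stage 2: fine-tuned lambda grid
      state1 <- loadArtifact(ws, "lasso_state1")
      grid <- refineGrid(state1, nPoints = cfg$gridPoints)
      folds <- makeFolds(n, cfg$lassoFolds, stepSeed(cfg$seed, 3L))
      bounds <- chunkBounds(ncol(Y), cfg$traitBlock)
      jobs <- lapply(seq_len(nrow(bounds)), function(b) {
        force(b)
        function() lassoCVBlock(X, Y[, bounds$start[b]:bounds$end[b],
                                     drop = FALSE], grid, folds)
      })
      res <- runJobs(ws, 3L, jobs, cfg$nWorkers)
      list(artifact = save("lasso_stage2", list(grid = grid, folds = folds,
                                                errs = res)),
           nJobs = length(jobs))
    },
    "4" = {  # combine stage-2 errors
      s2 <- loadArtifact(ws, "lasso_stage2")
      cvError <- Reduce(`+`, s2$errs)
      state <- new("LambdaSearchState", grid = s2$grid, cvError = cvError,
                   bestIndex = pickBest(cvError), stage = "fine")
      list(artifact = save("lasso_state2", state), nJobs = 1L)
    },
    "5" = {  # Marker Processing: lasso coefficients at best lambda, cap
      state2 <- loadArtifact(ws, "lasso_state2")
      B <- lassoMatrix(X, Y, state2@grid, state2@grid[state2@bestIndex])
      markers <- selectMarkers(B, cap = cfg$markerCap, pd = pd)
      list(artifact = save("markers", list(lassoB = B, markers = markers)),
           nJobs = 1L)
    },
    "6" = {  # trait network and connected components
      net <- correlationNetwork(pd@traits, threshold = cfg$networkThreshold,
                                sectionSize = cfg$correlationSection)
      comps <- connectedComponents(net)
      list(artifact = save("network", list(net = net, comps = comps)),
           nJobs = 1L)
    },
    "7" = {  # spectral clustering of oversized components
      nw <- loadArtifact(ws, "network")
      big <- which(lengths(nw$comps) > cfg$traitBlock)
      jobs <- lapply(big, function(i) {
        force(i)
        function() spectralSplit(nw$comps[[i]], nw$net, cap = cfg$traitBlock,
                                 seed = stepSeed(cfg$seed, 7L, i))
      })
      res <- runJobs(ws, 7L, jobs, cfg$nWorkers)
      parts <- c(nw$comps[setdiff(seq_along(nw$comps), big)],
                 do.call(c, c(res, list(list())))) # flatten split parts
      list(artifact = save("parts", parts), nJobs = max(length(jobs), 1L))
    },
    "8" = {  # Trait Processing: pack parts and assemble GFlasso blocks
      nw <- loadArtifact(ws, "network")
      parts <- loadArtifact(ws, "parts")
      partition <- packSubnetworks(parts, cap = cfg$traitBlock, net = nw$net)
      mk <- loadArtifact(ws, "markers")
      std <- standardizeForGFlasso(X[, mk$markers, drop = FALSE])
      blocks <- lapply(partition@groups, function(g) {
        sub <- subsetNetwork(nw$net, g)
        Yg <- sweep(Y[, g, drop = FALSE], 2L, colMeans(Y[, g, drop = FALSE]))
        list(X = std$X, Y = Yg, edges = sub@edges, traits = g,
             markers = mk$markers, scale = std$scale)
      })
      save("partition", partition)
      list(artifact = save("blocks", blocks), nJobs = 1L)
    },
    "9" = {  # GFlasso stage 1: lambda scan at gammaInit
      blocks <- loadArtifact(ws, "blocks")
      scale <- max(vapply(blocks, function(b) max(abs(crossprod(b$X, b$Y))), 0))
      lamGrid <- if (!is.null(cfg$lambdaGrid)) sort(unique(cfg$lambdaGrid), decreasing = TRUE)
                 else defaultGFGrid(scale, 0.01, 1, cfg$gridPoints)
      gamGrid <- if (!is.null(cfg$gammaGrid)) sort(unique(cfg$gammaGrid), decreasing = TRUE)
                 else defaultGFGrid(scale, 0.01, 10, cfg$gridPoints)
      gammaInit <- logMidpoint(gamGrid)
      save("gf_grids", list(lambdaGrid = lamGrid, gammaGrid = gamGrid,
                            gammaInit = gammaInit))
      sc <- runGFScan(ws, 9L, cfg, lamGrid, "lambda", gammaInit)
      list(artifact = save("gf_scan1", sc), nJobs = sc$nJobs)
    },
    "10" = {
      sc <- loadArtifact(ws, "gf_scan1")
      rec <- new("RegSearchRecord", stage = 1L, parameter = "lambda",
                 grid = sc$grid, fixedValue = sc$fixed, cvError = sc$cvError,
                 bestIndex = pickBest(sc$cvError))
      list(artifact = save("gf_rec1", rec), nJobs = 1L)
    },
    "11" = {  # GFlasso stage 2: gamma scan at the stage-1 best lambda
      grids <- loadArtifact(ws, "gf_grids")
      rec1 <- loadArtifact(ws, "gf_rec1")
      sc <- runGFScan(ws, 11L, cfg, grids$gammaGrid, "gamma",
                      rec1@grid[rec1@bestIndex])
      list(artifact = save("gf_scan2", sc), nJobs = sc$nJobs)
    },
    "12" = {
      sc <- loadArtifact(ws, "gf_scan2")
      rec <- new("RegSearchRecord", stage = 2L, parameter = "gamma",
                 grid = sc$grid, fixedValue = sc$fixed, cvError = sc$cvError,
                 bestIndex = pickBest(sc$cvError))
      list(artifact = save("gf_rec2", rec), nJobs = 1L)
    },
    "13" = {  # GFlasso stage 3: refined lambda scan at the stage-2 best gamma
      rec1 <- loadArtifact(ws, "gf_rec1")
      rec2 <- loadArtifact(ws, "gf_rec2")
      state <- new("LambdaSearchState", grid = rec1@grid,
                   cvError = rec1@cvError, bestIndex = rec1@bestIndex,
                   stage = "coarse")
      grid <- refineGrid(state, nPoints = m@config$gridPoints)
      sc <- runGFScan(ws, 13L, cfg, grid, "lambda", rec2@grid[rec2@bestIndex])
      list(artifact = save("gf_scan3", sc), nJobs = sc$nJobs)
    },
    "14" = {  # final validation, refit on all samples, write results
      sc <- loadArtifact(ws, "gf_scan3")
      rec <- new("RegSearchRecord", stage = 3L, parameter = "lambda",
                 grid = sc$grid, fixedValue = sc$fixed, cvError = sc$cvError,
                 bestIndex = pickBest(sc$cvError))
      save("gf_rec3", rec)
      lambdaBest <- sc$grid[rec@bestIndex]
      gammaBest <- sc$fixed
      blocks <- loadArtifact(ws, "blocks")
      mi <- list(); ti <- list(); wt <- list()
      for (b in blocks) {
        prob <- gflassoProblem(b$X, b$Y, b$edges, lambdaBest, gammaBest,
                               mu = cfg$mu, tol = cfg$tol,
                               maxIter = cfg$maxIter)
        sol <- fitGFlasso(prob)
        Bo <- sol@B / b$scale  # back to the original genotype scale
        nz <- which(Bo != 0, arr.ind = TRUE)
        if (nrow(nz)) {
          mi[[length(mi) + 1L]] <- b$markers[nz[, 1]]
          ti[[length(ti) + 1L]] <- b$traits[nz[, 2]]
          wt[[length(wt) + 1L]] <- Bo[nz]
        }
      }
      result <- AssociationResult(markerIds(pd), traitIds(pd),
                                  marker = unlist(c(mi, list(integer(0)))),
                                  trait = unlist(c(ti, list(integer(0)))),
                                  weight = unlist(c(wt, list(numeric(0)))),
                                  methodTag = "gflasso")
      writeAssociation(result, file.path(ws, "result.tsv"))
      writeCvReport(ws)
      list(artifact = save("result", list(result = result,
                                          lambda = lambdaBest,
                                          gamma = gammaBest)),
           nJobs = 1L)
    },
    stop(sprintf("unknown step %d", step))
  )
}

## per-stage CV report: stage, parameter, value, cv_error
writeCvReport <- function(ws) {
  rows <- list()
  for (nm in c("gf_rec1", "gf_rec2", "gf_rec3")) {
    rec <- loadArtifact(ws, nm)
    rows[[nm]] <- data.frame(stage = rec@stage, parameter = rec@parameter,
                             value = rec@grid, cv_error = rec@cvError)
  }
  rep <- do.call(rbind, rows)
  utils::write.table(rep, file.path(ws, "cv_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

## ---- public orchestration --------------------------------------------------

setStep <- function(m, i, ...) {
  upd <- list(...)
  for (nm in names(upd)) m@steps[[nm]][i] <- upd[[nm]]
  saveManifest(m)
  m
}

#' Run the pipeline
#'
#' Executes pending steps strictly sequentially, from the first non-done
#' step up to `until`. Within a step, jobs (trait blocks, folds,
#' sub-networks) run in parallel over `nWorkers` with per-job checkpoints;
#' a completed step is never re-run, so interrupted or paused runs resume
#' from their checkpoints. Input data are read only by the first step and
#' results are written only by the last. A failing job marks the step
#' `error` and halts the pipeline (restart or kill it).
#'
#' @param manifest a \linkS4class{PipelineManifest} (or a workspace path).
#' @param until run through this step index (default 14, the whole
#'   pipeline).
#' @return the updated manifest, invisibly when an error occurred. After
#'   step 14 the final \linkS4class{AssociationResult} is available via
#'   [pipelineResult()].
#' @export
runPipeline <- function(manifest, until = 14L) {
  m <- if (is.character(manifest)) loadManifest(manifest) else manifest
  m <- loadManifest(m@workspace)  # pick up on-disk state
  if (any(m@steps$status == "killed"))
    gfStop("gfmap_pipeline_error", "pipeline was killed; rebuild the manifest")
  for (i in seq_len(until)) {
    st <- m@steps$status[i]
    if (st == "done") next
    if (st == "error")
      gfStop("gfmap_pipeline_error",
             "step %d is in error state; restartPipeline() to retry", i)
    if (st == "paused")
      gfStop("gfmap_pipeline_error",
             "pipeline is paused at step %d; restartPipeline() to resume", i)
    m <- setStep(m, i, status = "running", started = format(Sys.time()))
    res <- tryCatch(executeStep(m, i), error = function(e) e)
    if (inherits(res, "error")) {
      m <- setStep(m, i, status = "error", error = conditionMessage(res))
      warning(sprintf("pipeline halted: step %d (%s) failed: %s", i,
                      m@steps$name[i], conditionMessage(res)))
      return(invisible(m))
    }
    m <- setStep(m, i, status = "done", n_jobs = res$nJobs,
                 jobs_done = res$nJobs, artifact = res$artifact,
                 finished = format(Sys.time()))
  }
  m
}

#' Pause, restart or kill a pipeline
#'
#' `pausePipeline` marks the first unfinished step paused; job checkpoints
#' already written are kept, so a later restart resumes without recomputing
#' them. `restartPipeline` clears paused/error marks (re-running only the
#' failed jobs of an errored step, thanks to the per-job checkpoints) and,
#' with `execute = TRUE`, resumes execution. `killPipeline` marks all
#' remaining steps killed; a killed pipeline cannot be restarted and writes
#' no further artifacts.
#'
#' @param manifest a \linkS4class{PipelineManifest} or workspace path.
#' @param execute for `restartPipeline`: resume running immediately.
#' @param until see [runPipeline()].
#' @return the updated manifest.
#' @export
pausePipeline <- function(manifest) {
  m <- if (is.character(manifest)) loadManifest(manifest) else loadManifest(manifest@workspace)
  i <- which(m@steps$status %in% c("pending", "running", "error"))[1]
  if (is.na(i))
    gfStop("gfmap_pipeline_error", "nothing to pause")
  setStep(m, i, status = "paused")
}

#' @rdname pausePipeline
#' @export
restartPipeline <- function(manifest, execute = TRUE, until = 14L) {
  m <- if (is.character(manifest)) loadManifest(manifest) else loadManifest(manifest@workspace)
  if (any(m@steps$status == "killed"))
    gfStop("gfmap_pipeline_error", "cannot restart a killed pipeline; rebuild it")
  for (i in which(m@steps$status %in% c("paused", "error", "running")))
    m <- setStep(m, i, status = "pending", error = "")
  if (execute) runPipeline(m, until = until) else m
}

#' @rdname pausePipeline
#' @export
killPipeline <- function(manifest) {
  m <- if (is.character(manifest)) loadManifest(manifest) else loadManifest(manifest@workspace)
  for (i in which(m@steps$status != "done"))
    m <- setStep(m, i, status = "killed")
  m
}

#' Pipeline progress report
#'
#' @param manifest a \linkS4class{PipelineManifest} or workspace path.
#' @return (invisibly) a data.frame with one row per step: index, name,
#'   stage, status, job counts and any captured error message. Printed in
#'   human-readable form.
#' @export
pipelineStatus <- function(manifest) {
  m <- if (is.character(manifest)) loadManifest(manifest) else loadManifest(manifest@workspace)
  show(m)
  err <- m@steps$error
  for (i in which(nzchar(err)))
    cat(sprintf("  step %d error: %s\n", i, err[i]))
  invisible(m@steps)
}

#' Final association result of a completed pipeline
#'
#' @param manifest a \linkS4class{PipelineManifest} or workspace path.
#' @return list with the \linkS4class{AssociationResult} (`result`) and the
#'   selected `lambda` and `gamma`.
#' @export
pipelineResult <- function(manifest) {
  m <- if (is.character(manifest)) loadManifest(manifest) else loadManifest(manifest@workspace)
  if (m@steps$status[14] != "done")
    gfStop("gfmap_pipeline_error", "pipeline has not completed step 14")
  loadArtifact(m@workspace, "result")
}
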