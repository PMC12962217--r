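# Single-file data container and the umbrella command-line interface.
#
# The container is one serialized file holding named datasets (all arrays
# in the package's index order) plus scalar attributes:
#   /kspace (Nd,Ns,Nc,Ny,Nx) complex    /mask (Nd,Ns,Ny,Nx)
#   /coils (Nc,Nz,Ny,Nx) complex        /shot_phases (optional)
#   /caipi (Nz,Ny) complex (optional)   /ground_truth (optional)
#   attrs: bvals, bvecs, mb_factor, n_shots, partial_fourier, version
# Complex datasets may be stored either natively or as paired real and
# imaginary arrays (a list with elements `real`, `imag`); both are read.

container_version <- "1.0"

pair_to_complex <- function(a, what) {
  if (is.list(a)) {
    if (!all(c("real", "imag") %in% names(a)))
      stop(sprintf("%s: paired storage needs 'real' and 'imag'", what))
    out <- a$real + 1i * a$imag
    dim(out) <- dim(a$real)
    return(out)
  }
  storage.mode(a) <- "complex"
  a
}

#' Write a reconstruction container
#'
#' @param path output file path.
#' @param kspace [kspace_data()] or complex array `(Nd,Ns,Nc,Ny,Nx)`.
#' @param mask sampling mask (taken from `kspace` if omitted).
#' @param coils coil maps `(Nc,Nz,Ny,Nx)`.
#' @param shot_phases optional shot phase maps (e.g. navigator maps).
#' @param caipi optional multi-band phase matrix.
#' @param ground_truth,recon optional image stacks.
#' @param bvals,bvecs,extra_attrs protocol metadata.
#' @return the path, invisibly.
#' @export
write_container <- function(path, kspace, mask = NULL, coils = NULL,
                            shot_phases = NULL, caipi = NULL,
                            ground_truth = NULL, recon = NULL,
                            bvals = NULL, bvecs = NULL,
                            extra_attrs = list()) {
  noise_sd <- NA_real_
  if (inherits(kspace, "kspace_data")) {
    mask <- kspace$mask
    noise_sd <- kspace$noise_sd
    kspace <- kspace$data
  }
  if (is.null(mask)) stop("mask is required")
  obj <- list(kspace = kspace, mask = mask, coils = coils,
              shot_phases = shot_phases, caipi = caipi,
              ground_truth = ground_truth, recon = recon,
              attrs = c(list(bvals = bvals, bvecs = bvecs,
                             noise_sd = noise_sd,
                             version = container_version), extra_attrs))
  saveRDS(obj, path)
  invisible(path)
}

#' Read and validate a reconstruction container
#'
#' Accepts complex datasets stored natively or as paired real/imaginary
#' arrays. Missing required datasets raise an error naming the dataset;
#' inconsistent shapes raise a validation error listing the offenders.
#'
#' @param path container file.
#' @return list with `kspace` ([kspace_data()]), `enc`
#'   ([encoding_operator()]) when coils are present, plus any optional
#'   datasets and the attribute list.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("container not found: %s", path))
  obj <- readRDS(path)
  for (req in c("kspace", "mask"))
    if (is.null(obj[[req]])) stop(sprintf("missing dataset: /%s", req))
  ks <- pair_to_complex(obj$kspace, "/kspace")
  mask <- obj$mask
  dk <- dim(ks); dm <- dim(mask)
  if (length(dk) != 5 || length(dm) != 4 ||
      !identical(as.integer(dm), as.integer(dk[c(1, 2, 4, 5)])))
    stop(sprintf(
      "shape inconsistency: /kspace %s vs /mask %s",
      paste(dk, collapse = "x"), paste(dm, collapse = "x")))
  attrs <- obj$attrs
  noise_sd <- if (!is.null(attrs$noise_sd)) attrs$noise_sd else NA_real_
  out <- list(kspace = kspace_data(ks, mask, noise_sd), attrs = attrs)
  if (!is.null(obj$coils)) {
    coils <- pair_to_complex(obj$coils, "/coils")
    Nz <- dim(coils)[2]
    phases <- if (!is.null(obj$shot_phases))
      pair_to_complex(obj$shot_phases, "/shot_phases")
    else array(1 + 0i, c(dk[1], dk[2], Nz, dk[4], dk[5]))
    caipi <- if (!is.null(obj$caipi)) pair_to_complex(obj$caipi, "/caipi")
    else array(1 + 0i, c(Nz, dk[4]))
    out$enc <- encoding_operator(coils, phases, caipi, mask)
    out$shot_phases <- if (!is.null(obj$shot_phases)) phases
  }
  for (nm in c("ground_truth", "recon"))
    if (!is.null(obj[[nm]])) out[[nm]] <- pair_to_complex(obj[[nm]], nm)
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `recon muse`, `recon llr`,
#' `recon unroll-train`, `recon unroll-infer`, `evaluate metrics` and
#' `evaluate dti`. Options are read from a YAML configuration file
#' (`--config`); every run logs the seeds and package version used.
#' Returns (rather than calls `quit()` with) the exit code so it can be
#' driven programmatically; the installed `dwirecon` script wraps it.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 on success).
#' @export
recon_main <- function(argv = character()) {
  usage <- paste(
    "usage: dwirecon <command> [options]",
    "commands:",
    "  simulate          --config cfg.yaml --out data.rds",
    "  recon muse        --in data.rds --out recon.rds [--gating self|nav]",
    "  recon llr         --in data.rds --out recon.rds [--config cfg.yaml]",
    "  recon unroll-train --in data.rds --model model.rds [--config cfg.yaml]",
    "  recon unroll-infer --in data.rds --model model.rds --out recon.rds",
    "  evaluate metrics  --in recon.rds --ref data.rds --out metrics.csv",
    "  evaluate dti      --in recon.rds --out dti.rds",
    sep = "\n")
  if (length(argv) == 0 || argv[1] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  opt <- function(name, default = NULL) {
    i <- which(argv == paste0("--", name))
    if (length(i) == 1 && i < length(argv)) argv[i + 1] else default
  }
  cfg <- if (!is.null(opt("config"))) yaml::read_yaml(opt("config")) else list()
  seed <- as.integer(cfg$seed %||% opt("seed", 1L))
  res <- try({
    cmd <- argv[1]
    sub <- if (length(argv) >= 2 && !startsWith(argv[2], "--")) argv[2] else ""
    message(sprintf("dwiunroll %s %s %s (seed %d)",
                    as.character(utils::packageVersion("dwiunroll")), cmd,
                    sub, seed))
    if (cmd == "simulate") {
      prot <- do.call(protocol_spec, modifyList(list(seed = seed),
                                                cfg$protocol %||% list()))
      n_y <- as.integer(cfg$n_y %||% 64L)
      sim <- simulate_kspace(prot, n_y = n_y, n_x = as.integer(cfg$n_x %||% n_y))
      write_container(opt("out", "simulated.rds"), sim$kspace,
                      coils = sim$enc$coils, shot_phases = sim$enc$phases,
                      caipi = sim$enc$mb, ground_truth = sim$truth,
                      bvals = prot$bvals, bvecs = prot$bvecs,
                      extra_attrs = list(mb_factor = prot$mb_factor,
                                         n_shots = prot$n_shots,
                                         partial_fourier = prot$partial_fourier,
                                         seed = seed))
    } else if (cmd == "recon" && sub == "muse") {
      dat <- read_container(opt("in"))
      gating <- opt("gating", "self")
      phi <- if (gating == "nav") {
        if (is.null(dat$shot_phases)) stop("no /shot_phases for navigated gating")
        dat$shot_phases
      } else {
        estimate_shot_phases(dat$kspace, dat$enc$coils, dat$enc$mb)
      }
      enc <- dat$enc
      enc$phases <- phi
      x <- muse_reconstruct(dat$kspace, enc)
      write_container(opt("out", "muse.rds"), dat$kspace,
                      coils = enc$coils, shot_phases = phi, caipi = enc$mb,
                      recon = x)
    } else if (cmd == "recon" && sub == "llr") {
      dat <- read_container(opt("in"))
      cfg_llr <- do.call(llr_config, cfg$llr %||% list())
      x <- admm_llr(dat$kspace, dat$enc, cfg_llr,
                    rho = cfg$rho %||% 0.05)
      write_container(opt("out", "llr.rds"), dat$kspace,
                      coils = dat$enc$coils, recon = x)
    } else if (cmd == "recon" && sub == "unroll-train") {
      dat <- read_container(opt("in"))
      ctl <- do.call(unroll_control, modifyList(list(seed = seed),
                                                cfg$unroll %||% list()))
      fit <- unroll_train(dat$kspace, dat$enc, ctl, verbose = TRUE)
      saveRDS(fit, opt("model", "model.rds"))
      losses <- data.frame(epoch = seq_along(fit$train_state$train_loss),
                           train = fit$train_state$train_loss,
                           valid = fit$train_state$valid_loss,
                           lambda = fit$train_state$lambda_trace)
      if (!is.null(opt("losses"))) write.csv(losses, opt("losses"),
                                             row.names = FALSE)
    } else if (cmd == "recon" && sub == "unroll-infer") {
      dat <- read_container(opt("in"))
      fit <- readRDS(opt("model"))
      x <- predict(fit, y = dat$kspace$data, enc = dat$enc)
      write_container(opt("out", "unroll.rds"), dat$kspace,
                      coils = dat$enc$coils, recon = x)
    } else if (cmd == "evaluate" && sub == "metrics") {
      rec <- read_container(opt("in"))
      ref <- read_container(opt("ref"))
      if (is.null(rec$recon) || is.null(ref$ground_truth))
        stop("need /recon in --in and /ground_truth in --ref")
      m <- data.frame(psnr = psnr(rec$recon, ref$ground_truth),
                      ssim = ssim(rec$recon, ref$ground_truth),
                      nrmse = nrmse(rec$recon, ref$ground_truth))
      write.csv(m, opt("out", "metrics.csv"), row.names = FALSE)
      print(m)
    } else if (cmd == "evaluate" && sub == "dti") {
      rec <- read_container(opt("in"))
      src <- rec$recon %||% rec$ground_truth
      if (is.null(src)) stop("container has neither /recon nor /ground_truth")
      tm <- fit_dti(Mod(src), rec$attrs$bvals, rec$attrs$bvecs)
      saveRDS(tm, opt("out", "dti.rds"))
    } else {
      cat(usage, "\n")
      stop(sprintf("unknown command: %s %s", cmd, sub))
    }
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    message(sprintf("error: %s", attr(res, "condition")$message))
    return(invisible(1L))
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
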