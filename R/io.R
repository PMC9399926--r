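#' @include simulate.R
NULL

#' Write / read a spike record as tab-separated text
#'
#' The format is a plain TSV with columns `time_ms`, `neuron_id`,
#' `population`, sorted by time, preceded by `#`-prefixed header lines that
#' carry the population sizes and protocol context, so the round trip is
#' lossless. Times are serialized with fixed microsecond precision, which
#' exceeds the simulation step and keeps the files diffable.
#'
#' @param x a [SpikeTrains-class].
#' @param path file path.
#' @return `writeSpikes` returns `path` invisibly; `readSpikes` returns the
#'   reconstructed [SpikeTrains-class].
#' @export
writeSpikes <- function(x, path) {
  stopifnot(is(x, "SpikeTrains"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf(
      "# sizes A=%d B=%d I=%d", x@sizes["A"], x@sizes["B"], x@sizes["I"]
    ),
    sprintf("# duration_ms %.6g", x@duration),
    sprintf("# stim_onset_ms %.6g", x@stimOnset),
    sprintf("# stim_end_ms %.6g", x@stimEnd),
    sprintf("# coherence %.10g", x@coherence),
    "time_ms\tneuron_id\tpopulation"
  ), con)
  if (length(x@time)) {
    writeLines(
      sprintf("%.3f\t%d\t%s", x@time, x@id, as.character(x@population)),
      con
    )
  }
  invisible(path)
}

#' @rdname writeSpikes
#' @export
readSpikes <- function(path) {
  lines <- readLines(path)
  headers <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    ln <- grep(paste0("^# ", key, " "), headers, value = TRUE)
    if (!length(ln)) stop("missing header '# ", key, "' in ", path)
    sub(paste0("^# ", key, " "), "", ln[1])
  }
  num <- function(key) {
    v <- meta(key)
    if (v %in% c("NA", "NaN")) NA_real_ else as.numeric(v)
  }
  sz <- meta("sizes")
  m <- regmatches(sz, regexec("A=(\\d+) B=(\\d+) I=(\\d+)", sz))[[1]]
  sizes <- structure(as.integer(m[2:4]), names = c("A", "B", "I"))
  body <- lines[!grepl("^#", lines)]
  df <- if (length(body) > 1) {
    read.delim(text = body, stringsAsFactors = FALSE)
  } else {
    data.frame(
      time_ms = numeric(0), neuron_id = integer(0),
      population = character(0)
    )
  }
  new("SpikeTrains",
    time = as.numeric(df$time_ms), id = as.integer(df$neuron_id),
    population = factor(df$population, levels = c("A", "B", "I")),
    sizes = sizes,
    duration = num("duration_ms"),
    stimOnset = num("stim_onset_ms"),
    stimEnd = num("stim_end_ms"),
    coherence = num("coherence")
  )
}

#' Write / read a trial-summary table
#'
#' Plain CSV with one row per trial (`trial`, `coherence_pct`, `seed`,
#' `winner`, `correct`, `decision_time_ms`, `persisted`, `delay_ratio`,
#' `tie`, `error`).
#'
#' @param summary the `summary` data.frame of [runBatch()].
#' @param path file path.
#' @export
writeTrialSummary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialSummary
#' @export
readTrialSummary <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

.configToList <- function(config) {
  np <- function(p) {
    list(
      v_rest = p@vRest, v_th = p@vTh, v_reset = p@vReset,
      tau_m = p@tauM, c_m = p@cM, t_ref = p@tRef
    )
  }
  ports <- config@ports
  list(
    sizes = as.list(config@sizes),
    neuron = list(
      excitatory = np(config@excParams),
      inhibitory = np(config@inhParams)
    ),
    ports = setNames(
      lapply(seq_len(nrow(ports)), function(i) {
        list(tau_syn = ports$tauSyn[i], delay = ports$delay[i])
      }),
      ports$label
    ),
    weights = list(
      J = config@J, w_plus = config@wPlus, w_minus = config@wMinus,
      w_nmda = config@wNMDA, w_within_ampa = config@wWithinAMPA,
      w_ie = config@wIE, w_ii = config@wII,
      w_noise_exc = config@wNoiseExc, w_noise_inh = config@wNoiseInh,
      w_stim = config@wStim
    ),
    epsilon = list(
      ee = config@epsEE, ei = config@epsEI, ie = config@epsIE,
      ii = config@epsII
    ),
    stimulus = list(
      mu0 = config@mu0, sigma0 = config@sigma0,
      update_interval = config@updateInterval
    ),
    noise = list(
      exc_mean = config@noiseExc[1], exc_sd = config@noiseExc[2],
      inh_mean = config@noiseInh[1], inh_sd = config@noiseInh[2]
    ),
    options = list(
      potentiate_within_ampa = config@potentiateWithinAMPA
    ),
    dt = config@dt
  )
}

#' Write / read a network configuration as YAML
#'
#' The YAML file mirrors the configuration structure (`sizes`, `neuron`,
#' `ports`, `weights`, `epsilon`, `stimulus`, `noise`, `options`, `dt`).
#' On reading, keys absent from the file fall back to the defaults of
#' [defaultConfig()]; unknown keys are rejected with the offending name so
#' that typos cannot silently change a simulation.
#'
#' @param config a [NetworkConfig-class].
#' @param path file path.
#' @return `readNetworkConfig` returns a validated [NetworkConfig-class].
#' @export
writeNetworkConfig <- function(config, path) {
  stopifnot(is(config, "NetworkConfig"))
  yaml::write_yaml(.configToList(config), path)
  invisible(path)
}

#' @rdname writeNetworkConfig
#' @export
readNetworkConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(
    "sizes", "neuron", "ports", "weights", "epsilon", "stimulus", "noise",
    "options", "dt"
  )
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  scale <- if (!is.null(raw$sizes$A)) raw$sizes$A / 800 else 1
  cfg <- defaultConfig(scale = scale)
  pick <- function(block, key, default, allowed) {
    if (is.null(raw[[block]])) return(default)
    bad <- setdiff(names(raw[[block]]), allowed)
    if (length(bad)) {
      stop(sprintf(
        "unknown key(s) under '%s': %s", block, paste(bad, collapse = ", ")
      ))
    }
    v <- raw[[block]][[key]]
    if (is.null(v)) default else v
  }
  if (!is.null(raw$sizes)) {
    cfg@sizes <- structure(
      as.integer(c(
        pick("sizes", "A", cfg@sizes["A"], c("A", "B", "I")),
        pick("sizes", "B", cfg@sizes["B"], c("A", "B", "I")),
        pick("sizes", "I", cfg@sizes["I"], c("A", "B", "I"))
      )),
      names = c("A", "B", "I")
    )
  }
  if (!is.null(raw$neuron)) {
    bad <- setdiff(names(raw$neuron), c("excitatory", "inhibitory"))
    if (length(bad)) {
      stop("unknown key(s) under 'neuron': ", paste(bad, collapse = ", "))
    }
    npKeys <- c("v_rest", "v_th", "v_reset", "tau_m", "c_m", "t_ref")
    readNP <- function(cls, base) {
      blk <- raw$neuron[[cls]]
      if (is.null(blk)) return(base)
      bad <- setdiff(names(blk), npKeys)
      if (length(bad)) {
        stop(sprintf(
          "unknown key(s) under 'neuron/%s': %s", cls,
          paste(bad, collapse = ", ")
        ))
      }
      g <- function(k, d) if (is.null(blk[[k]])) d else blk[[k]]
      neuronParams(
        g("v_rest", base@vRest), g("v_th", base@vTh),
        g("v_reset", base@vReset), g("tau_m", base@tauM),
        g("c_m", base@cM), g("t_ref", base@tRef)
      )
    }
    cfg@excParams <- readNP("excitatory", cfg@excParams)
    cfg@inhParams <- readNP("inhibitory", cfg@inhParams)
  }
  if (!is.null(raw$ports)) {
    bad <- setdiff(names(raw$ports), cfg@ports$label)
    if (length(bad)) {
      stop("unknown port(s): ", paste(bad, collapse = ", "))
    }
    for (lab in names(raw$ports)) {
      blk <- raw$ports[[lab]]
      bad <- setdiff(names(blk), c("tau_syn", "delay"))
      if (length(bad)) {
        stop(sprintf(
          "unknown key(s) under 'ports/%s': %s", lab,
          paste(bad, collapse = ", ")
        ))
      }
      i <- match(lab, cfg@ports$label)
      if (!is.null(blk$tau_syn)) cfg@ports$tauSyn[i] <- blk$tau_syn
      if (!is.null(blk$delay)) cfg@ports$delay[i] <- blk$delay
    }
  }
  wKeys <- c(
    "J", "w_plus", "w_minus", "w_nmda", "w_within_ampa", "w_ie", "w_ii",
    "w_noise_exc", "w_noise_inh", "w_stim"
  )
  cfg@J <- pick("weights", "J", cfg@J, wKeys)
  cfg@wPlus <- pick("weights", "w_plus", cfg@wPlus, wKeys)
  cfg@wMinus <- pick("weights", "w_minus", cfg@wMinus, wKeys)
  cfg@wNMDA <- pick("weights", "w_nmda", cfg@wNMDA, wKeys)
  wwa <- pick("weights", "w_within_ampa", cfg@wWithinAMPA, wKeys)
  cfg@wWithinAMPA <- if (is.null(wwa)) NA_real_ else as.numeric(wwa)
  cfg@wIE <- pick("weights", "w_ie", cfg@wIE, wKeys)
  cfg@wII <- pick("weights", "w_ii", cfg@wII, wKeys)
  cfg@wNoiseExc <- pick("weights", "w_noise_exc", cfg@wNoiseExc, wKeys)
  cfg@wNoiseInh <- pick("weights", "w_noise_inh", cfg@wNoiseInh, wKeys)
  cfg@wStim <- pick("weights", "w_stim", cfg@wStim, wKeys)
  eKeys <- c("ee", "ei", "ie", "ii")
  cfg@epsEE <- pick("epsilon", "ee", cfg@epsEE, eKeys)
  cfg@epsEI <- pick("epsilon", "ei", cfg@epsEI, eKeys)
  cfg@epsIE <- pick("epsilon", "ie", cfg@epsIE, eKeys)
  cfg@epsII <- pick("epsilon", "ii", cfg@epsII, eKeys)
  sKeys <- c("mu0", "sigma0", "update_interval")
  cfg@mu0 <- pick("stimulus", "mu0", cfg@mu0, sKeys)
  cfg@sigma0 <- pick("stimulus", "sigma0", cfg@sigma0, sKeys)
  cfg@updateInterval <- pick(
    "stimulus", "update_interval", cfg@updateInterval, sKeys
  )
  nKeys <- c("exc_mean", "exc_sd", "inh_mean", "inh_sd")
  cfg@noiseExc <- c(
    pick("noise", "exc_mean", cfg@noiseExc[1], nKeys),
    pick("noise", "exc_sd", cfg@noiseExc[2], nKeys)
  )
  cfg@noiseInh <- c(
    pick("noise", "inh_mean", cfg@noiseInh[1], nKeys),
    pick("noise", "inh_sd", cfg@noiseInh[2], nKeys)
  )
  cfg@potentiateWithinAMPA <- pick(
    "options", "potentiate_within_ampa", cfg@potentiateWithinAMPA,
    "potentiate_within_ampa"
  )
  if (!is.null(raw$dt)) cfg@dt <- raw$dt
  validObject(cfg)
  cfg
}

#' Write a network audit as JSON
#'
#' @param network a [DecisionNetwork-class].
#' @param path file path.
#' @seealso [networkAudit()]
#' @export
writeNetworkAudit <- function(network, path) {
  jsonlite::write_json(
    networkAudit(network), path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  invisible(path)
}

# rolling polynomial hash (two 31-bit lanes, exact in double arithmetic)
# over the serialized configuration list; stable across sessions for
# identical configurations
.configDigest <- function(config) {
  raw <- as.integer(serialize(.configToList(config), NULL, version = 2))
  h1 <- 0
  h2 <- 0
  for (b in raw) {
    h1 <- (h1 * 31 + b) %% 2147483629
    h2 <- (h2 * 131 + b) %% 2147483587
  }
  sprintf("%08x%08x", h1, h2)
}

#' Run manifest: the reproducibility record of a simulation
#'
#' A manifest captures everything needed to reproduce a run exactly: the
#' configuration digest, the master seed and its four derived substream
#' seeds, the package version, a timestamp and the output paths. Re-running
#' the same configuration with the manifest's master seed reproduces the
#' outputs bit for bit.
#'
#' @param config the [NetworkConfig-class] of the run.
#' @param seed master seed of the run.
#' @param outputs character vector of output paths.
#' @return a named list (the manifest).
#' @export
runManifest <- function(config, seed, outputs = character()) {
  list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "DecisionNet",
    version = as.character(utils::packageVersion("DecisionNet")),
    config_digest = .configDigest(config),
    master_seed = as.integer(seed),
    stream_seeds = as.list(deriveSeeds(seed)),
    outputs = as.list(outputs)
  )
}

#' @rdname runManifest
#' @param manifest a manifest list.
#' @param path file path.
#' @export
writeRunManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname runManifest
#' @export
readRunManifest <- function(path) {
  jsonlite::read_json(path)
}
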