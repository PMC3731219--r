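# Readers and writers: FASTA, Vienna dot-bracket text, gate
# specification files and run configuration.

#' Read / write RNA FASTA
#'
#' Standard FASTA via Biostrings. On read, T (DNA alphabet) is
#' normalized to U with a warning; records round-trip identically.
#'
#' @param path file path.
#' @param seqs for `writeFastaRNA`, a list of
#'   [NucleotideSequence-class] or a named character vector.
#' @return `readFastaRNA` returns a (possibly empty) list of
#'   [NucleotideSequence-class].
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeFastaRNA(c(a = "ACGU"), tf)
#' readFastaRNA(tf)
#' @export
readFastaRNA <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(list())
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    if (grepl("T", s)) {
      warning(sprintf("record '%s': DNA alphabet converted to RNA (T -> U)",
                      names(set)[i]))
      s <- gsub("T", "U", s)
    }
    out[[i]] <- nucleotideSequence(s, name = names(set)[i])
  }
  out
}

#' @rdname readFastaRNA
#' @export
writeFastaRNA <- function(seqs, path) {
  if (is.character(seqs)) {
    nms <- names(seqs)
    if (is.null(nms)) nms <- paste0("seq", seq_along(seqs))
    seqs <- mapply(nucleotideSequence, seqs, name = nms, SIMPLIFY = FALSE)
  }
  set <- Biostrings::BStringSet(vapply(seqs, residues, character(1)))
  names(set) <- vapply(seqs, function(s) s@name, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write Vienna dot-bracket records
#'
#' The Vienna dialect: an optional `>name` header, an optional sequence
#' line, and a structure line with an optional trailing energy in
#' parentheses. `&` separates the strands of a complex.
#'
#' @param path file path.
#' @param structure a [DotBracket-class] or [FoldResult-class] for
#'   writing.
#' @param name record name used when writing.
#' @return `readDotBracket` returns
#'   `list(name=, sequence=, structure=, energy=)` (`NA` for absent
#'   fields), with `structure` a validated [DotBracket-class].
#' @examples
#' tf <- tempfile(fileext = ".db")
#' writeDotBracket(foldMFE("GGGAAAACCC"), tf)
#' readDotBracket(tf)$structure
#' @export
readDotBracket <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(.inputError("empty dot-bracket file"))
  name <- NA_character_
  if (startsWith(lines[1L], ">")) {
    name <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  sequence <- NA_character_
  if (length(lines) && grepl("^[ACGUTacgut&]+$", lines[1L])) {
    sequence <- gsub("T", "U", toupper(lines[1L]))
    lines <- lines[-1L]
  }
  if (!length(lines)) stop(.inputError("no structure line found"))
  m <- regmatches(lines[1L],
                  regexec("^([.()&]+)(\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?\\s*$",
                          lines[1L]))[[1L]]
  if (!length(m)) {
    stop(.inputError(sprintf("cannot parse structure line: '%s'", lines[1L])))
  }
  energy <- if (nchar(m[4L])) as.numeric(m[4L]) else NA_real_
  db <- dotBracket(m[2L])
  if (!is.na(sequence) &&
      nchar(gsub("&", "", sequence)) != sum(db@strandLengths)) {
    stop(.inputError("sequence and structure lengths differ"))
  }
  list(name = name, sequence = sequence, structure = db, energy = energy)
}

#' @rdname readDotBracket
#' @export
writeDotBracket <- function(structure, path, name = NA_character_) {
  lines <- character(0)
  if (!is.na(name)) lines <- c(lines, paste0(">", name))
  if (is(structure, "FoldResult")) {
    seqs <- character(length(structure@strandLengths))
    off <- 0L
    for (k in seq_along(structure@strandLengths)) {
      seqs[k] <- substr(structure@sequence, off + 1L,
                        off + structure@strandLengths[k])
      off <- off + structure@strandLengths[k]
    }
    lines <- c(lines, paste(seqs, collapse = "&"),
               sprintf("%s (%.2f)", structure@structure@symbols,
                       structure@energy))
  } else {
    lines <- c(lines, dotBracket(structure)@symbols)
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- gate specification files ----------------------------------------

#' Read / write gate specification files
#'
#' Lossless YAML serialization of a [GateSpec-class]: gate type,
#' species (role, length, target structure, motifs, fixed sequences),
#' truth-table entries, reactions and objective terms. Files are
#' validated on read.
#'
#' @param gate a [GateSpec-class].
#' @param path file path.
#' @return `readGateSpec` the validated [GateSpec-class];
#'   `writeGateSpec` the path invisibly.
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' writeGateSpec(makeNotGate(), tf)
#' readGateSpec(tf)
#' @export
writeGateSpec <- function(gate, path) {
  obj <- list(
    gate_type = gate@gateType,
    species = lapply(gate@species, function(s) {
      out <- list(name = s@name, role = s@role, length = s@length,
                  target_structure = s@targetStructure)
      if (length(s@motifs)) {
        out$motifs <- lapply(s@motifs, function(m) list(seq = m$seq,
                                                        at = m$at))
      }
      if (!is.na(s@fixedSequence)) out$fixed_sequence <- s@fixedSequence
      out
    }),
    entries = lapply(gate@entries, function(e) {
      list(inputs = as.list(e$inputs), required_output = e$requiredOutput)
    }),
    reactions = lapply(gate@reactions, function(rx) {
      list(participants = as.list(rx$participants), sense = rx$sense)
    }),
    terms = lapply(gate@terms, function(tm) {
      out <- list(kind = tm@kind, weight = tm@weight, entry = tm@entry)
      if (tm@kind == "kin") {
        out$participants <- as.list(tm@participants)
        out$sense <- tm@sense
      } else {
        out$subject <- as.list(tm@subject)
        if (!is.na(tm@target)) out$target <- tm@target
        if (length(tm@maskPos)) {
          out$mask_positions <- as.list(tm@maskPos)
          out$mask_state <- tm@maskState
        }
      }
      out
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeGateSpec
#' @export
readGateSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("gate_type", "species", "entries", "reactions", "terms")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop(.specError(paste("gate file missing field(s):",
                          paste(missing, collapse = ", "))))
  }
  species <- lapply(obj$species, function(s) {
    speciesSpec(
      name = s$name, role = s$role, length = s$length,
      targetStructure = s$target_structure,
      motifs = if (is.null(s$motifs)) list() else
        lapply(s$motifs, function(m) list(seq = m$seq, at = as.integer(m$at))),
      fixedSequence = if (is.null(s$fixed_sequence)) NA_character_ else
        s$fixed_sequence)
  })
  entries <- lapply(obj$entries, function(e) {
    list(inputs = as.character(unlist(e$inputs)),
         requiredOutput = e$required_output)
  })
  reactions <- lapply(obj$reactions, function(rx) {
    list(participants = as.character(unlist(rx$participants)),
         sense = rx$sense)
  })
  terms <- lapply(obj$terms, function(tm) {
    if (tm$kind == "kin") {
      .kinTerm(as.character(unlist(tm$participants)), tm$sense,
               weight = tm$weight, entry = tm$entry)
    } else {
      .strTerm(as.character(unlist(tm$subject)),
               target = if (is.null(tm$target)) NA_character_ else tm$target,
               maskPos = if (is.null(tm$mask_positions)) integer(0) else
                 as.integer(unlist(tm$mask_positions)),
               maskState = if (is.null(tm$mask_state)) NA_character_ else
                 tm$mask_state,
               weight = tm$weight, entry = tm$entry)
    }
  })
  gate <- new("GateSpec", gateType = obj$gate_type, species = species,
              entries = entries, reactions = reactions, terms = terms)
  validateGateSpec(gate)
  gate
}

# ---- run configuration -----------------------------------------------

.RUNCONFIG_KEYS <- list(
  objective = c("Gp", "dGsat", "alphaSat", "RT", "wKin", "wStr", "seedGU"),
  optimizer = c("iterations", "T0", "Tend", "wordLenStart", "moveMix",
                "rngSeed", "harmonicStiffness", "homodimerThreshold",
                "maxIdenticalRun", "resampleBudget"),
  top = c("objective", "optimizer", "engine", "output", "logLevel")
)

#' Read / write a run configuration file
#'
#' YAML configuration covering the objective constants, the optimizer
#' settings, the engine selection and output options. Unknown keys are
#' rejected; a configuration round-trips losslessly.
#'
#' @param path file path.
#' @param config for writing, a list as returned by `readRunConfig`:
#'   `list(objective = <ObjectiveConfig>, optimizer = <OptimizerConfig>,
#'   engine =, output =, logLevel =)`.
#' @return `readRunConfig` the configuration list with S4 config
#'   objects filled in.
#' @export
readRunConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  unknown <- setdiff(names(obj), .RUNCONFIG_KEYS$top)
  if (length(unknown)) {
    stop(.inputError(paste("unknown configuration key(s):",
                           paste(unknown, collapse = ", "))))
  }
  objArgs <- obj$objective
  unknown <- setdiff(names(objArgs), .RUNCONFIG_KEYS$objective)
  if (length(unknown)) {
    stop(.inputError(paste("unknown objective key(s):",
                           paste(unknown, collapse = ", "))))
  }
  optArgs <- obj$optimizer
  unknown <- setdiff(names(optArgs), .RUNCONFIG_KEYS$optimizer)
  if (length(unknown)) {
    stop(.inputError(paste("unknown optimizer key(s):",
                           paste(unknown, collapse = ", "))))
  }
  engine <- if (is.null(obj$engine)) "reference" else obj$engine
  if (!engine %in% c("reference", "vienna")) {
    stop(.inputError(sprintf("unknown engine '%s'", engine)))
  }
  list(
    objective = do.call(objectiveConfig, as.list(objArgs)),
    optimizer = do.call(optimizerConfig, as.list(optArgs)),
    engine = engine,
    output = obj$output,
    logLevel = if (is.null(obj$logLevel)) "info" else obj$logLevel
  )
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  oc <- config$objective
  pc <- config$optimizer
  obj <- list(
    objective = list(Gp = oc@Gp, dGsat = oc@dGsat, alphaSat = oc@alphaSat,
                     RT = oc@RT, wKin = oc@wKin, wStr = oc@wStr,
                     seedGU = oc@seedGU),
    optimizer = list(iterations = pc@iterations, T0 = pc@T0, Tend = pc@Tend,
                     wordLenStart = pc@wordLenStart, moveMix = pc@moveMix,
                     rngSeed = pc@rngSeed,
                     harmonicStiffness = pc@harmonicStiffness,
                     homodimerThreshold = pc@homodimerThreshold,
                     maxIdenticalRun = pc@maxIdenticalRun,
                     resampleBudget = pc@resampleBudget),
    engine = config$engine
  )
  if (!is.null(config$output)) obj$output <- config$output
  if (!is.null(config$logLevel)) obj$logLevel <- config$logLevel
  yaml::write_yaml(obj, path)
  invisible(path)
}

.engineModel <- function(engine) {
  switch(engine,
    reference = referenceEnergyModel(),
    vienna = viennaEnergyModel(),
    stop(.inputError(sprintf("unknown engine '%s'", engine))))
}
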