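# Lesion simulation: a memory system bundles the autoassociative store, the
# generative network (encoder and decoder treated as separable pathways) and
# the semantic readout. Lesioning disables one pathway; calls through a
# lesioned pathway signal a typed condition, everything else stays intact.

#' Assemble a memory system
#'
#' @param store A [hopfield_store()] (or NULL).
#' @param vae A trained `vae` (or NULL).
#' @param readout A [fit_readout()] classifier (or NULL).
#' @return An object of class `memory_system` with no lesions.
#' @export
memory_system <- function(store = NULL, vae = NULL, readout = NULL) {
  structure(list(store = store, vae = vae, readout = readout,
                 lesions = character()),
            class = "memory_system")
}

#' Lesion a component of a memory system
#'
#' @param system A [memory_system()].
#' @param component One of `"mhn"`, `"encoder"`, `"decoder"`, `"readout"`.
#' @return The lesioned system; operations through the removed pathway raise
#'   a condition of class `genmem_lesion_error`.
#' @export
lesion <- function(system, component = c("mhn", "encoder", "decoder",
                                         "readout")) {
  stopifnot(inherits(system, "memory_system"))
  component <- match.arg(component)
  system$lesions <- union(system$lesions, component)
  system
}

lesion_check <- function(system, component) {
  if (component %in% system$lesions) {
    stop(structure(class = c("genmem_lesion_error", "error", "condition"),
                   list(message = sprintf("pathway '%s' is lesioned",
                                          component),
                        call = sys.call(-1L))))
  }
}

#' Episodic recall through a memory system
#'
#' Generative reconstruction of a partial input (encoder and decoder
#' pathways required; survives an MHN lesion for consolidated memories).
#'
#' @param system A [memory_system()].
#' @param partial Input image.
#' @return The reconstructed image.
#' @export
system_recall <- function(system, partial) {
  lesion_check(system, "encoder")
  lesion_check(system, "decoder")
  recall_basic(system$vae, partial)
}

#' Semantic recall through a memory system
#'
#' Classifies the latent representation of the input; requires the encoder
#' and readout but not the decoder or the MHN.
#'
#' @param system A [memory_system()].
#' @param partial Input image.
#' @return Predicted label(s).
#' @export
system_semantic_recall <- function(system, partial) {
  lesion_check(system, "encoder")
  lesion_check(system, "readout")
  semantic_recall(system$vae, system$readout, partial)
}

#' Autoassociative retrieval through a memory system
#'
#' @param system A [memory_system()].
#' @param query Query vector.
#' @return A `retrieval_result` (see [hopfield_retrieve()]).
#' @export
system_retrieve <- function(system, query) {
  lesion_check(system, "mhn")
  hopfield_retrieve(system$store, query)
}
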