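# one full hierarchical run under the default study conditions,
# computed once and shared by the tests that examine its properties
.pipelineCache <- new.env(parent = emptyenv())

defaultPipelineRun <- function() {
    if (!is.null(.pipelineCache$run)) return(.pipelineCache$run)
    params <- simulationParams()
    truth <- generateStructure(params)
    map <- simulateContacts(truth$structure, params)
    res <- suppressWarnings(
        runHierarchical(map, domains = truth$domains))
    .pipelineCache$run <- list(params = params, truth = truth,
                               map = map, res = res)
    .pipelineCache$run
}
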