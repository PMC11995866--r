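{
  "title": "result_record",
  "description": "Serialized record of one pipeline stage: stage name, input file digests, echoed parameters, stage-specific outputs, seed and timestamp.",
  "required": ["stage", "inputs", "parameters", "outputs", "seed", "timestamp"],
  "properties": {
    "stage": {"type": "string"},
    "inputs": {
      "type": "object",
      "description": "named entries, each {path: string, md5: string}"
    },
    "parameters": {"type": "object"},
    "outputs": {"type": "object"},
    "seed": {"type": ["integer", "null"]},
    "timestamp": {"type": "string", "description": "ISO-8601"}
  }
}
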