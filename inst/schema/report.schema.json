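{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dream-bench report",
  "type": "object",
  "required": ["command", "parameters", "results"],
  "properties": {
    "command": { "type": "string" },
    "parameters": { "type": "object" },
    "results": { "type": "object" }
  }
}
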