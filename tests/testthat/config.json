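{"seed":1,"preset":"sham","gt":[],"geometry":[],"program":[],"controller":[],"analysis":{"smoothing":0.95,"k":3,"blanking_ms":0.5,"search_window_ms":[0.5,5],"target_mv":"NA","duration_min":30}}
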