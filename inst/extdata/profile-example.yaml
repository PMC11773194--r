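# Example community rule set: start from the strict profile, escalate
# non-standard connections to errors, and silence the unattached
# material/medium notice.
name: strict
severity_overrides:
  R3: error
  R5: info
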