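{
  "version": "1.0",
  "comment": "Indication-resolved therapeutic INR intervals. Valve ranges follow the originating centre's clinical practice; override per deployment as needed.",
  "ranges": {
    "AORTIC_VALVE": [1.5, 2.0],
    "MITRAL_VALVE": [1.7, 2.5],
    "TRICUSPID_VALVE": [2.0, 2.5],
    "ATRIAL_FIBRILLATION": [2.0, 3.0],
    "VTE": [2.0, 3.0]
  }
}
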