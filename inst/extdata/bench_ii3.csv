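method,accuracy,kappa
winner,89.3,0.783
deep-network,88.2,0.764
CNN-SAE,90.0,0.800
IS-CBAM-CNN,90.7,0.814
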