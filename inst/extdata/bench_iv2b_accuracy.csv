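subject,CapsNet,BP-SVM,BP-SVM_std,CNN-SAE,CNN-SAE_std,IS-CBAM-CNN,IS-CBAM-CNN_std
1,78.8,65.4,4.7,76.0,2.7,80.3,1.5
2,55.7,58.5,4.3,65.8,1.9,75.0,1.8
3,55.0,64.4,5.9,75.3,1.8,67.7,2.6
4,95.9,92.7,4.6,95.3,0.4,95.4,0.6
5,83.1,77.1,6.6,83.0,1.4,88.3,1.5
6,83.4,71.4,6.8,79.5,2.5,80.0,1.7
7,75.6,68.4,7.6,74.5,1.8,73.7,2.2
8,91.2,68.8,5.9,75.3,2.6,77.4,2.0
9,87.1,65.9,6.1,73.3,3.6,78.6,2.1
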