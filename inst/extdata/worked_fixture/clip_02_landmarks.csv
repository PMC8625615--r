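"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,21.38,21.79,24.45,25.64,29.82,36.17,42.31,48.77,56.18,64.05,68.75,74.78,80.37,83.09,89.17,91.86,91.42,26.13,31.1,36.37,42.82,47.1,67.69,70.33,75.67,78.73,85.53,58.15,56.8,57.48,56,48.4,51.64,57.57,60.43,65.36,44.7,40.83,32.31,28.46,34.41,39.87,83.56,78.89,72.12,69.93,72.19,79.95,71.79,70.26,62.71,56.16,47.95,43.44,40.15,41.76,49.58,56.54,63.89,70.28,66.3,64.49,54.6,48.49,45.92,47.18,56.93,62.36,53.08,60.74,67.5,74.85,82.91,86.63,92.17,91.62,94.04,93.61,92.72,87.6,83.69,75.59,68.96,60.81,50.83,33.07,33.23,31.69,32.11,31.96,31.79,31.12,30.32,30.55,33.03,41.87,46.52,51.42,57.07,59.72,61.43,61.04,60,58.98,41.57,37.97,37.46,40.33,43.97,43.57,39.21,38.57,38.19,40.06,42.29,43.42,73.53,70.4,69.72,65.73,67.77,69.55,71.5,77.71,81.06,81.08,80.88,76.57,74.3,70.7,69.81,70.88,74.93,76.63,77.38,77.52
2,22.67,23.2,24.73,27.58,33.4,38.28,45.26,51.06,56.73,64.93,69.29,75.44,81.61,86.35,88.52,92.07,91.93,29.33,34.68,37.81,41.73,47.97,69.44,72.24,77.84,81.28,85.79,58.13,57.77,56.95,57.68,48.25,53.48,57.58,61.53,66.22,47.85,41.26,35,31.85,34.99,43.06,84.27,79.76,75.43,70.8,74.79,80.44,73.72,71.52,64.28,56.93,48.24,43.7,43.75,44.27,51.27,58.5,65.95,70.76,66.71,64.99,58.05,48.43,48.95,51.01,58.56,62.42,50.25,60.48,67.77,76.84,84.15,87.16,92.5,94.38,97.44,92.96,92.29,88.37,82.09,74.84,69.11,60.58,52.7,32.88,31.78,31.35,32.53,32.8,32.12,33.07,30.41,30.78,31.97,42.73,46.74,51.15,57.03,60.93,60.54,62.6,61.84,58.48,40.79,39.25,38.9,40.79,42.83,43.08,40.06,36.49,39.26,40.56,43.27,43.22,73.99,72.03,65.74,65.31,67.92,71.37,73.98,76.48,82.31,83.63,81.11,76.16,72.6,72.05,70.47,73.63,73.72,77.97,77.04,75.94
3,22.32,21.06,24.51,25.3,29.84,36.8,42.95,49.94,57.44,61.09,68.8,76.51,80.2,86.08,89.26,91.46,91.33,26.22,32.14,37.51,41.42,47.86,65.38,71.57,78.26,81.3,84.26,55.11,56.4,56.53,56.74,49.37,53.67,56.01,58.72,64.89,44.85,40.6,35.09,30.7,32.64,42.34,84.91,79.22,73.68,71.26,73.81,78.57,72.34,70.91,64.84,55.6,47.39,42.58,39.48,43,49.48,56.2,63.25,70.33,70.68,63.48,58.04,51.59,47.39,49.56,58,64.4,50.21,59.75,67.82,75.52,81.44,87.88,90.95,91.94,95.13,94.02,90.13,85.57,80.99,75.11,66.2,58.92,50.47,33.2,30.53,29.5,30.05,32.68,31.83,29.23,28.36,30.53,30.74,40.23,44.32,50.03,54.81,58,61.28,61.44,61.36,60.54,39.66,37.35,39.59,36.7,45,41.55,37.43,35.75,37.05,39.61,42.54,39.54,72.7,69.27,67.1,65.57,67.2,68.34,74.68,78.55,82.7,81.13,79.97,74.33,74.41,68.85,68.28,69.85,71.76,75.34,76.75,77.09
4,21.19,17.48,23,24.76,29.19,36.32,40.92,48.12,55.3,61.41,66.96,73.78,77.32,83.98,85.5,88.51,90.82,26.7,27.72,34.62,37.42,44.27,64.56,70.66,75.04,79.38,83.83,53.72,54.28,54.04,53.81,43.89,49.34,52.6,56.29,60.82,42.82,37.66,31.05,27.97,31.27,38.43,79.33,77.57,70.95,67.16,70.53,76.39,69.77,67.88,61.63,53.9,46.52,41.07,38.54,40.17,48.32,55.46,60.96,68.09,66.1,61.66,55.2,46.24,46.05,47.81,54.52,60.78,50.06,57.91,69.64,74.99,82.86,86.57,90.76,92.63,94.81,90.83,90.47,85.67,82.14,74.52,64.51,58.22,52.02,32.86,30.41,30.18,30.5,31.71,31.53,30.09,26.51,27,30.81,39.8,45.44,50.31,55.09,58.71,59.06,60.49,59.45,59.47,39.6,36.29,35.34,38.89,43.67,41.04,36.5,37.38,38.09,39.18,41.2,41.67,72.25,68.31,65.08,63.04,64.97,67.2,71.29,76.6,79.57,81.85,78.65,74.64,72.03,71.88,68.75,70.42,73.13,76.11,76.7,74.64
5,20.77,20.8,19.44,23.67,31.12,33.21,40.14,47.5,52.27,59.36,64.89,73.9,78.7,84.85,86.86,87.96,90.06,25.52,30.04,32.53,37.95,45,63.78,69.63,73.48,78.81,83.42,55.84,55.96,51.37,53.56,45.63,50.16,54.26,59.37,62.42,41.45,35.21,31.56,27.35,30.58,39.1,79.18,77.48,68.62,67.6,71.88,77.32,68.81,65.69,61.74,53.96,44.39,39.78,37.82,41.33,47.65,55.43,60.84,67.06,64.02,60.41,55.06,47.73,45.58,46.51,54.31,58.81,49.92,60.87,66.41,74.64,82.76,86.94,91.16,92.58,93.58,92.37,89.58,86.95,80.83,74.44,65.53,58.48,53.27,29.71,30.76,30.18,31.26,29.69,32.43,31.5,28.28,30.15,31.84,39.73,45.54,49.64,55.73,57.24,62.18,60.08,60.04,57.94,41.2,37.51,37.05,37.19,41.92,41.69,37.95,36.15,37.6,38.77,41.13,43.77,74.4,70.18,64.26,66.3,67.05,67.71,74.55,75.92,79.89,83.09,80.75,77.8,73.45,70.44,70.49,70.8,72.92,73.69,78.3,75.3
6,18.77,18.1,18.99,23.87,28.73,33.1,39.98,46.85,53.23,58.73,67.82,74.83,76.64,83.86,86.06,89.71,89.04,24.6,29.5,34.63,39.06,43.96,64.37,67.33,74.22,78.52,81.79,54.17,54.59,53.36,54.43,45.36,50.16,51.96,57.37,60.8,44.05,36.87,32,26.09,29.98,36.61,81.57,75.06,71.53,66.2,70.31,77.87,68.56,66.64,61.67,52.96,45.26,40.24,38.42,37.53,47.59,54.58,60.64,66.58,65.33,62.6,53.32,45.27,44.01,45.32,53.91,58.41,50.87,61.89,66.5,75.42,83.41,88.98,91.21,93.52,94.61,93.51,91.95,87,82.54,74.88,67.23,60.06,53.1,32.11,31.59,30.57,31.95,31.76,31.69,30.98,29.83,28.71,32.09,39.88,44.39,50.03,56.54,58.04,60.5,61.93,61.55,59.71,39.1,38.56,36.47,37.35,40.66,43.55,40.24,38.13,38.21,37.84,41.03,42.22,71.51,69.37,66.8,65.61,65.58,67.92,73.94,77.96,78.94,80.38,79.77,77.8,72.22,69.78,68.4,68.57,73.41,76.17,75.37,75.58
7,23.63,20.4,23.35,25,31.74,36.82,41.54,50.2,55.82,62.8,68.71,76.89,80.01,86.8,88.91,93.93,93.55,26.97,32.21,37.01,41.13,46.6,67.54,69.33,77.14,80.16,85.54,56.76,57.51,55.65,55.68,48.52,52.47,55.11,59.37,62.76,44.85,40.6,33.86,31.52,33,39.9,83.53,80.28,74.2,70.87,72.64,79.07,72.72,70.04,64.48,57.95,47.21,42.6,43.14,43.32,49.53,57.9,63.01,69.07,65.81,65.57,56.37,49.02,46.82,50.01,58.8,64.08,50.44,59.41,65.36,73.47,81.89,85.65,91.71,93.02,94.38,92.32,92.55,86.68,81.86,73.22,68.37,58.53,55.18,31.73,29.98,29.61,30.35,30.77,32.72,29.89,28.03,30.16,31.69,40.28,43.15,49.36,55.55,59.11,57.8,60.78,59.53,56.54,40.69,36.23,36.08,36.56,41.71,39.88,37.4,40.02,37.21,38.71,41.43,41.96,72.89,68.72,65.51,63.76,64.8,69.69,70.75,76.9,78.94,79.7,80.02,76.22,72.51,70.21,69.31,71.11,72.85,74.1,75.78,76.04
8,23,22.23,23.24,26.69,32.58,38.28,43.13,48.97,57.54,62.5,71.07,76.61,81.13,86.15,88.84,92.01,94.32,27.43,30.28,36.49,39.62,46.49,68.14,70.48,77.4,80.61,86.59,55.23,56.14,57.4,56.54,44.88,52.31,55.98,58.12,65.55,44.49,40.27,33.91,29.36,31.5,40.24,81.37,78.76,72.59,68.31,71.59,78.89,73.16,71.35,63.9,56.21,48.64,42.21,40.68,41.39,51.74,55.01,64.47,70,67.28,64.62,56.6,47.54,46.95,49.2,57.09,62.68,52.13,58.76,66.53,76.57,82.93,88.69,90.31,93.61,95.74,95.14,91.02,86.96,83.7,76.77,66.44,59.3,52.21,32.62,31.94,31.49,31.59,32.67,33.68,31.57,30.24,30.92,32.38,40.16,44.51,50.69,55.74,61.38,60.48,61.28,62.22,59.55,40.87,37.13,38.09,39.73,42.4,41.49,38.82,37.25,37.19,40.21,43.96,43.01,72.78,69.43,67,65.84,66.7,70.63,72.06,77.58,81.33,80.35,79.45,77.43,73.64,70.35,70.13,70.83,74.44,75.28,76.9,77.34
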