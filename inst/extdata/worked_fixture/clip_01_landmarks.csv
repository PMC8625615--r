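"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,22.7,24.19,23.25,25.42,32.44,36.78,42.96,51.26,56.4,64.4,71.6,75.54,80.37,88.44,91.05,93.2,95.47,27.23,32.95,39.2,44.59,49.3,67.36,72.33,77.78,79.78,88.28,58.22,58.46,56.52,57.95,49.42,54.09,57.39,61.42,65.32,45.93,41.25,35.96,29.26,33.47,43.28,84.18,80.14,74.28,71.56,75.87,80.79,73.21,71.58,66.33,57.87,49.95,43.36,41.84,42.22,50.02,58.3,67.27,69.18,67.58,64.09,57.33,50.16,47.82,51.84,57.16,63.72,53.87,62.4,68.72,76.51,83.33,88.46,94,94.22,97.13,94.66,92.69,87.74,81.57,75.35,68.34,60.74,54.93,33.85,31.47,31.63,31.74,34.91,33.56,31.29,29.62,32.31,30.97,42.18,46.58,52.04,56.72,59.96,61.63,62.32,62.73,59.14,43.45,39.75,38.14,39.61,44.74,43.98,39.19,38.47,38.98,40.9,43.38,43.39,74.61,73.91,67.75,68.53,68.32,70.96,73.47,80.42,81.89,83.34,82.52,77.27,75,72.85,72.59,74.77,75.55,77.16,81.29,76.47
2,22.33,21.21,25.02,27.16,32.68,38.44,45.16,51.6,58.12,61.36,68.54,78.12,79.81,85.29,89.03,92.2,91.48,26.67,30.86,38.48,42.13,45.96,66.41,72.08,76.91,80.8,86.04,54.35,56.12,55.81,55.73,47.5,54.44,56.07,59.08,67.31,46.24,39.94,33.69,29.16,33.97,40.21,83.21,80.6,74.04,70.67,74.67,80.84,72.24,72.25,63.75,56.03,47.33,43.49,41.17,44.27,49.58,57.03,66.2,69.57,65.74,64.03,58.09,49.64,46.93,49.66,56.69,63.47,50.42,59.83,65.99,73.98,80.62,85.39,88.51,90.71,93.22,91.01,91.47,86.26,81.9,73.17,65.37,57.62,51.07,31.09,31.02,29.58,30.97,30.94,32.88,30.12,27.05,29.6,29.34,40.02,43.21,47.15,54.08,55.48,57.94,60.71,58.5,57.56,38.16,36.59,37.36,38.23,41.52,43.14,36.63,36.38,36.78,37.91,42.25,41.5,70.44,68.62,65.38,63.77,66.83,70.17,70.24,75.01,78.24,79.96,79.06,75.89,71.47,71.03,67.78,67.44,72.4,75.35,75.49,74.17
3,22.73,22.11,23.67,27.28,34.53,37.01,41.98,48.73,56.61,62.46,69.03,77.08,80.05,86.36,87.89,91.58,90.85,28.45,32.15,38.69,40.86,46.84,66.74,70,78.59,81.97,86.46,55.67,58.01,55.36,55.75,48.47,53.19,56.4,59.58,65.22,45.17,40.76,34.19,28.96,33.12,41.36,82.04,80.9,72.96,68.66,72.4,79.86,71.64,70.9,63.8,55.86,46.17,42.58,40.65,41.8,50.25,58.37,64.71,68.99,67.31,64.13,56.07,49.35,47.77,48.55,55.96,61.44,50.96,59,68.61,74.53,81.8,87.79,91.67,93.38,94.7,93.06,90.95,87.74,82.41,74.74,67.01,58.82,50.58,30.27,30.25,30.7,30.89,32.61,35.06,30.25,27.65,30.3,30.67,41.02,44.28,51.34,55.34,58.85,60.22,61.34,61.61,58.09,40.83,36.07,37.36,39.09,42.25,42.03,38.14,38.61,38.47,40.51,44.68,41.45,72.86,71.98,66.25,65.76,66.31,68.96,72.62,77.25,79.97,83.55,83.65,78.33,74.01,73.14,69.85,71.71,73.76,76.75,76.98,76.69
4,20.64,21.23,23.6,26.19,30.5,34.63,39.74,48.44,54.85,62.15,68.65,75.64,80.02,86.48,85.69,89.96,89.41,25.22,31.05,35.95,37.96,46.08,63.81,69.54,74.89,79.77,83.48,54.15,55.16,53.24,53.98,46.85,51.38,54.36,61.08,62.73,43.86,38.27,31.56,30.78,33.21,39.05,82.78,78.28,72.15,69.64,70.76,78.23,70.19,66.93,63.97,57.3,46.93,41.11,38.52,40.63,48.33,57.22,64.27,69.53,62.87,63.12,54.85,49.45,46.82,44.4,56.5,61.69,54,62.18,67.34,76.12,84.64,88.07,92.4,93.34,95.99,93.15,90.8,85.5,82.53,75.55,68.36,60.91,52.83,32.48,33.49,30.16,31.28,32.63,31.59,30.06,29.93,30.14,31.02,40.83,44.54,50.38,54.78,59.25,61.12,62.18,62.22,57.88,40.6,37.37,39.52,39.26,42.4,42.82,39.64,37.91,39.31,40,43.46,44.22,71.79,70.13,68.15,63.7,67.45,70.09,74.72,79.11,81.06,81.93,81.89,76.62,73.91,70.91,69.51,72.12,74.3,77.1,79.28,77.27
5,20.64,20.4,23.04,24.56,31.08,36.43,40.44,46.61,53.71,60.45,68.6,74.85,79.26,85.98,86.53,88.72,89.47,25.66,27.63,35.3,39.99,44.02,66.52,69.3,75.07,80.12,82.39,53.65,56.18,52.99,54.89,46.21,47.82,55.18,58.51,63.1,43.32,38.09,34.04,29.52,29.31,39.86,82.88,76.28,70.19,66.64,69.2,78.62,69.18,68.14,61.83,53.37,45.21,41.78,36.26,40.62,48.01,54.61,61.85,68.51,66.42,62.61,55.06,45.33,44.57,48.11,55.91,58.2,49.74,59.06,65.55,75.21,81.82,84.45,91.59,92.12,91.98,91.61,91.18,86.96,79.38,73.51,65.28,56.72,49.95,31.59,29.48,27.84,28.99,32.92,30.91,28.89,27.35,29.58,29.64,40.28,43.3,50.06,53.16,58.78,60.81,60.28,59.69,58.54,40.41,37.68,35.73,37.27,40.67,40.92,37.43,36.68,37.48,37.68,41.89,41.92,72.63,70.32,66.66,65.79,66.72,66.62,71.09,77.68,78.34,81.96,78.93,76.05,71.25,70.3,69.14,67.74,71.65,74.55,74.9,76.63
6,19.08,19.92,20.46,22.3,29.91,32.67,39.03,45.63,51.14,61.67,65.09,74.3,75.6,81.89,85.17,88.56,89.04,23.39,28.66,33.49,40.41,42.27,64.38,67.65,74.87,79.17,83.59,52.73,53.68,53.67,52.31,43.07,48.91,52.22,56.7,61.54,42.82,36.27,31.39,27.79,31.32,37.69,78.9,77.81,68.92,66.33,69.59,77.09,69.79,66.73,59.37,52.96,44.75,40.85,38.12,39.5,45.28,52.94,60.96,66.88,64.05,60.41,52.89,46.75,46.39,43.79,53.39,58.64,51.06,59.81,67.64,74.87,80.47,86.86,88.89,92.15,91.69,92.61,89.85,85.75,81.75,74.08,65.67,58.27,53.43,30.7,30.43,28.98,29.83,32.93,31.59,30.11,29.75,28.86,32.81,40.87,44.19,51.26,54.12,58.43,59.09,60.9,58.77,58.32,38.92,38.24,37.42,37.73,40.28,40.79,36.42,37.84,35.59,39.03,41.79,41.86,70.35,69.12,64.46,62.9,65.21,69.58,72.24,75.81,77.48,81.56,78.49,75.81,71.81,70.46,67.23,70.22,71.82,73.85,76.94,74.91
7,19.51,19.79,19.4,22.72,29.48,32.82,42.25,46.19,54.53,60.08,65.41,73.67,76.47,81.12,84.78,89.05,88.86,24.71,28.73,33.97,37.88,43.5,65.01,68.46,72.95,78.09,80.8,55.34,52.98,53.47,52.32,43.73,50.29,55.31,58.63,60.81,42.95,37.97,31.21,29.45,29.59,39.32,81.23,76.38,71.49,66.81,70.48,77.94,69.9,66.94,61.76,52.37,45.64,40.45,38.09,40.35,47.41,52.67,60.34,66.41,63.68,59.94,54.69,45.93,45.46,45.68,53.87,59.92,52.16,62.08,68.02,76.81,81.83,87.34,90.59,93.96,95.37,92.26,90.78,88.15,82.13,74.83,65.87,58.83,51.14,31.9,30.5,31.89,30.8,32.02,31.12,29.17,28.07,30.18,30.91,40.86,45.74,50.77,57.45,59.87,61.72,60.82,62.04,59.84,41.11,36.79,37.78,37.97,45.07,41.55,39.19,38.22,39.42,37.64,43.51,43.69,74.21,70.49,68.28,66.36,68.42,69.5,75.63,79.27,82.38,81.8,82.11,79.86,74.94,70.79,70,69.7,74.1,76.82,79.15,75.81
8,19.8,19.58,22.6,24.17,30.67,35.88,41.32,47.62,53.91,61.08,67.92,72.55,76.81,83.78,86.47,89.19,89.97,23.97,30.86,35.2,40.46,45.06,64.91,69.42,75.24,79.91,82.58,53.72,54.85,53.35,52.07,46.48,49.78,52.9,56.96,60.74,43.32,37.88,32.04,28.29,30.38,39.58,82.19,75.89,69.38,65.47,70.08,77.09,70.17,67.37,62.6,53.46,47.11,42.61,38.28,40.58,48.04,54.44,62.73,67.93,64.1,63.56,53.35,47.46,46.29,45.94,54.54,60.53,49.83,58.51,67.83,75.52,82.88,87.6,92.48,91.47,92.77,92.23,90.71,87.83,80.28,74.35,65.52,59.56,50.82,30.71,31.04,29.66,30.74,31.76,30.49,29.44,29.39,29.47,32.27,40.26,43.79,49.61,55.09,58.26,59.96,61.56,59.75,59.04,40.52,35.89,37.78,36.57,44.27,42.18,40.01,37.16,36.34,40.23,42.02,41.62,73.67,68.6,64.91,63.51,65.62,68.64,72.73,77.1,79.88,80.48,80.21,77.65,73.26,67.23,68.06,69.49,70.89,73.72,76.85,73.95
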