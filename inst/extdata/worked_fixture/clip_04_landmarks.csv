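"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,24.36,20.86,26.88,27.3,33.82,40.59,43.02,50.49,57.81,62.85,69.53,76.11,82.06,88.35,90.1,93.47,94.93,29.71,34.68,38.47,43.28,48.73,67.31,72.09,78.42,82.42,85.24,58.49,57.3,57.88,57.12,49.1,54.86,57.2,59.96,66.97,47.07,39.53,33.75,30.4,36.49,42.37,82.7,82.45,74.24,71.38,74.05,79.57,74.66,71.65,66.37,57.86,48.38,44.48,42.91,44.44,49.49,56.8,64.91,69.29,69.68,65.4,58.11,49.81,49.05,49.89,58.35,64.04,48.77,57.49,63.3,72.32,78.05,82.98,88.93,89.93,92.37,89.79,89.19,84.01,79.99,72.36,64.59,56.94,49.62,29.73,29.08,29.14,27.51,29.16,29.26,28.36,25.8,28.8,29.75,38.99,42.9,48.48,54.02,56.91,58.09,60.67,57.42,56.09,37.35,34.77,35.2,35.49,41.21,40.04,34.18,36.68,33.63,34.67,39.99,40.16,74.07,69.18,65.61,63.09,66.06,68.92,72.49,77.48,79.34,82.16,80.94,76.83,73.28,69.96,65.96,69.42,73.78,75.56,74.58,76.42
2,21.83,21.96,26.05,28.09,32.62,36.58,41.89,50.19,58.78,63.83,70.34,78.8,80.75,85.5,89.21,91.38,92.64,28.13,31.61,37.34,41.74,47.25,66.97,71.06,75.37,82.56,86.5,56.51,57.13,55.58,58.07,48.63,51.78,58.69,60.53,65.75,44.68,40.84,34.28,31.29,34.09,40.14,84.11,80,75.69,70.63,74.1,80.28,74,70.44,64.31,54.71,47.67,44.63,40.76,44.08,49.11,57.84,62.42,68.62,68.96,63.78,56.91,48.42,48.4,49.58,57.72,62.2,51.06,61,68.42,78.14,83.03,85.68,92.04,92.44,94.49,93.67,90.95,88.3,82.35,75.76,67.79,60.76,52.94,32.18,30.48,30.55,31.82,31.91,33.67,30.76,28.83,30.85,32.29,41.22,45.86,50.7,53.68,59.04,61.62,61.97,60.91,59.45,39.56,36.72,37.36,38.19,40.78,42.11,38.4,37.89,37.31,39.29,41.96,43.69,71.73,68.07,64.91,64.07,66.1,68.51,73.21,77.55,79.99,81.31,79.86,78.12,73.64,70.19,69.96,72.48,73.84,74.65,75.34,75.2
3,21,19.64,22.98,25.5,31.13,34.84,39.98,48.37,53.56,63.29,67.3,75.12,79.17,83.15,86.92,90.22,90.71,25.35,30.59,35.79,39.88,46.99,64.56,70.46,76.04,80.94,83.99,55.4,55.54,54.43,55.8,46.39,49.39,54.35,58.7,62.9,43.71,38.42,34.09,27.68,30.18,38.13,81.45,77.98,72.35,67.76,71.97,76.94,71.05,67.57,62.26,56.34,47.74,40.35,39.61,41.03,48.48,54.56,62.34,69,64.99,63.49,54.32,46.69,45.1,47.48,56.2,61.45,50.43,59.86,68.64,74.53,84.22,86.55,90.66,92.94,93.51,91.86,90.59,87.89,81.76,74.96,68.5,59.5,51.45,31.95,29.85,31.84,30.44,30.39,29.19,29.56,28.19,28.6,31.22,40.25,42.87,52.11,56.9,58.58,59.73,61.79,59.29,60.78,39.44,38.56,37.54,35.39,42.68,42.63,36.66,37.11,38.72,39.16,41.52,41.43,72.79,70.1,66.76,62.08,67.03,66.96,72.35,76.66,80.47,80.48,80.53,76.57,71.43,69.97,67.05,70.12,71.24,75.66,73.95,76.21
4,21.64,20.25,22.33,26.6,31.49,36.28,40.99,49.48,55.07,61.5,67.18,75.56,78.5,84,89.72,89.53,89.71,26.81,30.15,34.67,41.28,46.85,64.67,69.68,73.85,79.8,85.07,52.87,55.28,54.28,55.04,46.15,51.82,53.89,59.94,64.21,42.44,40.23,31.41,27.15,32.56,37.86,81.65,76.16,70.65,67.33,71.37,80.68,69.79,67.12,63.46,54.15,45.79,41.47,37.41,40.64,47.55,55.32,62.04,66.58,65.83,64.23,56.14,46.49,45.96,47.28,57.45,61.46,49.67,57.2,65.74,73.25,81.3,84.79,89.19,91.22,91.94,92.66,90.21,86.24,80.5,73.89,65.44,58.61,49.31,29.78,28.12,27.73,29.37,30.63,31.04,26.15,24.77,27.02,30.39,38.19,42.7,47.45,52.63,57.41,61.14,59.62,57.93,56.77,38.54,36.25,35.66,36.36,40.88,39.97,36,36.03,36.27,37.42,41.39,40.5,75.94,70.81,66.79,66.01,67.54,70.5,73.97,77.35,81.87,83.35,80.93,76.68,73.68,70.91,69.32,72.59,71.99,76.86,76.32,74.6
5,20.09,18.6,20.79,24.32,30.83,34.81,40.05,47.79,53.48,59.66,68.06,74.26,77.34,84.16,85.14,89.69,89.88,24.15,29.99,33.44,38.63,44.71,64.76,68.05,74.16,79.72,81.95,55.59,55.62,51.89,52.58,44.4,49.89,54.08,57.76,60.89,42.79,37.15,32.27,28.37,31.41,37.94,81.33,75.87,70.82,67.76,70.57,77.38,69.88,67.69,61.45,54.83,45.69,41.37,40.57,40.35,48.49,54.65,60.17,68.35,64.15,61.05,54.53,46.71,43.99,46.61,55.13,59.81,49.91,58.99,66.45,74.83,79.78,85.67,89.34,91.67,93.75,91.37,88.84,85.88,79.72,72.56,64.07,58.16,49.36,30.73,27.83,28.68,29.36,30.44,29.46,28.52,26.88,29.21,29.43,38.26,43.5,49.25,53.52,57.69,57.19,59.7,58.2,56.64,38.8,35.48,35.64,34.68,40.17,38.83,36.57,37.13,36.66,38.51,40.32,39.6,71.13,67.53,64.04,64.03,64.93,65.87,69.51,74.51,76.8,77.38,76.36,74.22,71.79,67.99,67.63,69.42,71.49,74.34,78.01,73.1
6,19.95,19.68,23.08,25.8,28.86,33.45,39.49,45.9,52.98,61.41,67.13,74.65,78.46,82.94,86.99,89.7,91.65,25.5,30.39,33.39,38.83,45.64,65.64,70.68,75.21,80.03,83.17,54.27,56.84,54.24,55.24,45.82,50.14,56.22,57.77,65.06,44.02,37.85,32.67,27.61,32.16,37.67,83.08,77.83,69.42,69.21,70.32,79.26,70.03,67.54,63.11,53.86,46.62,40.98,38.05,40.79,47.49,54.02,60.73,67.52,66.09,62.76,55.39,45.64,45.85,47.73,54.51,60.1,51.38,61.53,68.47,73.76,82.84,85.92,91.36,92.29,95.21,93.84,90.48,87.03,82.25,73.97,67.01,59.53,50.67,32.35,29.96,27.69,29.95,33.37,31.09,30.55,28.26,27.87,31.62,41.17,43.7,47.63,55.94,58.03,60.53,60.8,59.95,58.83,40.29,36.87,37.27,39.98,41.87,41.09,39.51,38.57,36.86,38.42,42.82,43.91,76.38,71.76,70.15,65.81,68.04,71.77,74.66,80.77,81.55,82.88,82.89,77.98,74.63,72.89,70.21,73.7,74.63,76.89,79.41,78.74
7,19.16,20.42,23.94,23.68,30.96,34.52,40.1,47,53.78,60.34,65.69,76.12,78.34,82.76,86.31,91.1,89.52,23.44,30.41,35.48,38.1,46.38,64.08,68.08,73.59,79.62,83.24,54.25,56.22,53.16,53.02,44.74,49.57,53.33,59.19,63.38,41.48,37.48,31.13,29.2,32.95,37.81,80.8,77.19,69.07,67.71,69.62,78.06,69.47,66.77,62.31,54.15,42.4,39.62,37.43,39.95,47.44,55.65,61.66,64.76,66.19,61.21,53.99,45.92,45.01,47.99,56.07,61.42,53.99,61.82,69.73,76.01,82.48,88.41,90.7,93.53,96.52,92.43,92.42,87.18,82.17,76.54,66.59,61,54.8,32.81,32.16,32.26,30.45,34.41,32.9,31.11,28.59,30.33,34.73,41.43,45.96,52.06,56.9,59,62.06,62.36,62.86,58.27,41.24,39.72,38.86,40.08,43.82,42.76,40.62,37.07,38.66,41,44.71,44.07,76.68,71.73,70.97,66.91,67.6,71.25,77.52,80.16,84.01,84.99,83.61,78.48,78.58,72.63,74.98,74.98,76.15,78.5,80.58,78.97
8,19.87,19.74,21.5,25.87,29.9,35.46,40.67,48.25,54.79,62.22,67.56,74.4,78.13,84.13,86.73,89.04,90.72,26.81,29.34,38.34,38.87,46.24,66.55,70.93,75.01,80.99,82.97,54.55,55.57,55.35,53.08,46.51,50.83,54.39,59.92,63.05,43.82,40.24,32.2,29.04,30.99,40.34,82.38,77.97,73.65,68.86,71.27,78.1,70.27,69.49,62.43,54.27,45.59,42.75,37.63,40.16,49.51,56.16,62.09,67.04,64.22,62.77,57.9,47.77,45.71,48.76,57.48,60.81,49.45,59.97,68.09,74.36,82.32,87.52,90.36,93.78,94.84,93.22,90.19,86.65,81.39,75.28,67.32,58.88,53.22,33.2,30.01,31.9,30.04,33.35,32.98,30.58,29.47,27.95,30.96,40.18,42.27,49.93,55.99,59.39,60.11,58.72,61.44,59.58,40.49,37.88,35.62,37.1,42.08,42.56,39.32,37.38,36.44,38.31,42.21,41.54,73.79,71.61,69.51,65.63,68.02,69.05,74.45,78.9,83.69,81.83,82.33,78.65,73.31,73.72,71.12,73.57,76.52,76.3,78.97,78.78
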